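# BED region IO. BED is natively 0-based half-open, which is also the
# package-internal convention, so coordinates pass through unchanged.

#' Read a BED file into a region tibble
#'
#' Accepts 3- to 6-column BED. Coordinates are kept in BED's native 0-based
#' half-open convention; chromosome names are normalised with
#' [normalize_chrom()]. Rows without a name column are named
#' `"chrom:start-end"`. Names must be unique within one file.
#'
#' @param path Path to the BED file.
#' @param kind Region kind label stored in the `kind` column, one of
#'   `"fragile_site"`, `"gene"`, `"exon"`, `"element"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (`"+"`, `"-"` or `"."`), `kind`.
#' @seealso [write_bed()]
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr4\t90127394\t91605295\tFRA4F", bed)
#' read_bed(bed, kind = "fragile_site")
#' @export
read_bed <- function(path, kind = c("fragile_site", "gene", "exon", "element")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), name = character(),
                          strand = character(), kind = character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    abort(sprintf("BED line %d: fewer than 3 columns.", which(n_col < 3)[1]))
  }
  get <- function(i, default = NA_character_) {
    purrr::map_chr(fields, function(f) if (length(f) >= i) f[i] else default)
  }
  chrom <- normalize_chrom(get(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (any(is.na(start)) || any(is.na(end))) abort("BED: non-numeric coordinates.")
  name <- get(4)
  auto <- is.na(name) | name == "."
  name[auto] <- sprintf("%s:%d-%d", chrom[auto], start[auto], end[auto])
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        name = name, strand = strand, kind = kind)
  validate_regions(out, sprintf("BED file '%s'", path))
  out
}

#' Write a region tibble to a BED6 file
#'
#' @param regions Region tibble (see [read_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  strand <- if ("strand" %in% names(regions)) regions$strand else "."
  lines <- sprintf("%s\t%s\t%s\t%s\t0\t%s",
                   regions$chrom,
                   format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   regions$name, strand)
  writeLines(lines, path)
  invisible(path)
}
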