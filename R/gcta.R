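#' Parse GCTA .hsq result files into a partition table
#'
#' Each `.hsq` file is the whitespace/tab-delimited output of a GCTA REML
#' run with a header line `Source Variance SE`; the `V(G)/Vp` row carries
#' the h2c estimate (field 2) and its standard error (field 3). One record
#' is produced per file, paired with the supplied per-chromosome size.
#'
#' @param paths character vector of `.hsq` file paths, one per chromosome.
#' @param sizes numeric vector of size values, same length as `paths`.
#' @param chrom optional chromosome labels; defaults to the file base names.
#' @param size_column whether `sizes` are SNP counts (`"n_snp"`, default)
#'   or base-pair lengths (`"size_bp"`).
#' @return A [partition_table].
#' @export
parse_gcta_hsq <- function(paths, sizes, chrom = NULL,
                           size_column = c("n_snp", "size_bp")) {
  size_column <- match.arg(size_column)
  if (length(paths) != length(sizes)) {
    stop("validation error: ", length(paths), " .hsq files but ",
         length(sizes), " size values", call. = FALSE)
  }
  if (is.null(chrom)) chrom <- sub("\\.hsq$", "", basename(paths))
  est <- vapply(paths, .parse_one_hsq, c(0, 0))
  args <- list(chrom = chrom, h2c = est[1, ], se = est[2, ],
               size_column = size_column,
               provenance = paste0("gcta_hsq:", length(paths), " files"))
  args[[size_column]] <- sizes
  do.call(partition_table, args)
}

.parse_one_hsq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  hit <- which(vapply(fields, function(f) f[1] == "V(G)/Vp", TRUE))
  if (!length(hit)) {
    stop("format error: no 'V(G)/Vp' row in ", path, call. = FALSE)
  }
  f <- fields[[hit[1]]]
  if (length(f) < 3) {
    stop("format error: 'V(G)/Vp' row in ", path,
         " has fewer than 3 fields", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(f[2:3]))
  if (any(is.na(vals))) {
    stop("format error: non-numeric estimate/SE in 'V(G)/Vp' row of ",
         path, call. = FALSE)
  }
  vals
}
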