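#' Construct a chromosome partitioning table
#'
#' A partition table holds one row per chromosome with the data needed for
#' the size regression and for HC-correction: a chromosome label, at least
#' one size proxy (chromosome length in bp and/or SNP count), the h2c
#' estimate, and its standard error.
#'
#' @param chrom character vector of unique chromosome labels.
#' @param h2c numeric vector of per-chromosome variance proportions
#'   (non-negative after censoring).
#' @param se numeric vector of standard errors of `h2c`; strictly positive.
#' @param size_bp optional numeric vector of chromosome lengths in base
#'   pairs; required if `n_snp` is absent.
#' @param n_snp optional numeric vector of per-chromosome SNP counts;
#'   required if `size_bp` is absent.
#' @param size_column which size proxy the regression uses, `"n_snp"` or
#'   `"size_bp"`. Defaults to `"n_snp"` when SNP counts are present
#'   (the convention for simulated tables), else `"size_bp"`.
#' @param provenance free-text source tag stored as an attribute.
#'
#' @return A `data.frame` of class `"partition_table"` with attributes
#'   `size_column` and `provenance`.
#' @examples
#' pt <- partition_table(chrom = paste0("chr", 1:5),
#'                       n_snp = c(400, 300, 200, 120, 60),
#'                       h2c   = c(0.04, 0.05, 0.01, 1e-6, 0.02),
#'                       se    = c(0.02, 0.017, 0.014, 0.011, 0.008))
#' pt
#' @export
partition_table <- function(chrom, h2c, se, size_bp = NULL, n_snp = NULL,
                            size_column = NULL, provenance = "constructed") {
  chrom <- as.character(chrom)
  df <- data.frame(chrom = chrom, stringsAsFactors = FALSE)
  if (!is.null(size_bp)) df$size_bp <- as.numeric(size_bp)
  if (!is.null(n_snp)) df$n_snp <- as.numeric(n_snp)
  df$h2c <- as.numeric(h2c)
  df$se <- as.numeric(se)
  if (is.null(size_column)) {
    size_column <- if (!is.null(n_snp)) "n_snp" else "size_bp"
  }
  attr(df, "size_column") <- size_column
  attr(df, "provenance") <- provenance
  class(df) <- c("partition_table", "data.frame")
  validate_partition_table(df)
}

#' Validate a partition table
#'
#' Checks the invariants every downstream computation relies on: at least
#' three rows, unique chromosome labels, at least one size column, strictly
#' positive standard errors, and a resolvable `size_column` attribute.
#'
#' @param x object to validate.
#' @return `x` invisibly-validated (returned unchanged) or an error.
#' @export
validate_partition_table <- function(x) {
  if (!is.data.frame(x)) stop("partition table must be a data.frame", call. = FALSE)
  req <- c("chrom", "h2c", "se")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("partition table format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!any(c("size_bp", "n_snp") %in% names(x))) {
    stop("partition table format error: missing column(s) size_bp or n_snp",
         call. = FALSE)
  }
  if (nrow(x) < 3) {
    stop("partition table validation error: need >= 3 chromosomes, got ",
         nrow(x), call. = FALSE)
  }
  if (anyDuplicated(x$chrom)) {
    stop("partition table validation error: duplicated chromosome label(s): ",
         paste(unique(x$chrom[duplicated(x$chrom)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x$se) | x$se <= 0)
  if (length(bad)) {
    stop("partition table validation error: non-positive SE for chromosome(s) ",
         paste(x$chrom[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$h2c))) {
    stop("partition table validation error: non-finite h2c values", call. = FALSE)
  }
  sc <- attr(x, "size_column")
  if (is.null(sc)) sc <- if ("n_snp" %in% names(x)) "n_snp" else "size_bp"
  if (!sc %in% names(x)) {
    stop("partition table validation error: size_column '", sc,
         "' not present in table", call. = FALSE)
  }
  if (any(!is.finite(x[[sc]]) | x[[sc]] <= 0)) {
    stop("partition table validation error: non-positive size values in '",
         sc, "'", call. = FALSE)
  }
  attr(x, "size_column") <- sc
  if (!inherits(x, "partition_table")) class(x) <- c("partition_table", class(x))
  x
}

# Regressor values of a partition table (the chosen size proxy).
.size_values <- function(table) {
  table[[attr(table, "size_column")]]
}

#' Read a partition table from TSV
#'
#' The file is UTF-8, tab-delimited with a header line; `#`-prefixed lines
#' are ignored; the decimal separator is `.`. The header must contain
#' `chrom`, `h2c`, `se` and at least one of `size_bp`, `n_snp`.
#'
#' @param path path to the TSV file.
#' @param size_column size proxy to use as the regressor; default picks
#'   `n_snp` when available, else `size_bp`.
#' @return A [partition_table] with rows in file order.
#' @seealso [write_partition_table()]
#' @export
read_partition_table <- function(path, size_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("chrom", "h2c", "se")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("partition table format error: missing column(s) ",
         paste(miss, collapse = ", "), " in ", path, call. = FALSE)
  }
  partition_table(chrom = df$chrom, h2c = df$h2c, se = df$se,
                  size_bp = if ("size_bp" %in% names(df)) df$size_bp,
                  n_snp = if ("n_snp" %in% names(df)) df$n_snp,
                  size_column = size_column, provenance = path)
}

#' Write a partition table to TSV
#'
#' Values are serialized at full precision (17 significant digits) so that a
#' write/read round trip reproduces the table bit-exactly.
#'
#' @param table a [partition_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(table, path) {
  table <- validate_partition_table(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @export
print.partition_table <- function(x, ...) {
  cat(sprintf("Chromosome partitioning table: %d chromosomes (regressor: %s)\n",
              nrow(x), attr(x, "size_column")))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  source:", prov, "\n")
  print.data.frame(x, ...)
  invisible(x)
}
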