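# Bundled genome presets. Only the *relative* chromosome sizes enter any
# computation in this package (SNP allocation is multinomial by length).
# human22: GRCh37 autosome lengths (bp), chromosomes 1-22.
# chicken28: the 28 largest Gallus gallus autosomes (all >= 1 Mb), lengths
# approximating the GRCg6a-era reference assembly; micro-chromosomes below
# 1 Mb are excluded because they carry too few SNPs for a stable fit.
.genome_presets <- list(
  human22 = data.frame(
    chrom = paste0("chr", 1:22),
    size_bp = c(249250621, 243199373, 198022430, 191154276, 180915260,
                171115067, 159138663, 146364022, 141213431, 135534747,
                135006516, 133851895, 115169878, 107349540, 102531392,
                90354753, 81195210, 78077248, 59128983, 63025520,
                48129895, 51304566),
    stringsAsFactors = FALSE
  ),
  chicken28 = data.frame(
    chrom = paste0("chr", 1:28),
    size_bp = c(197608386, 149682049, 110838418, 91315245, 59809098,
                36374701, 36742308, 30219446, 24153086, 21119840,
                20200042, 20387278, 19166714, 16219308, 13062184,
                2844601, 10762512, 11373140, 11087614, 15349816,
                6859504, 5249288, 6251846, 6379958, 3011219,
                5349051, 5228753, 5437364),
    stringsAsFactors = FALSE
  )
)

#' Load a bundled genome preset
#'
#' Two presets are bundled: `"human22"`, the 22 human autosomes (GRCh37
#' lengths, 48--249 Mb), and `"chicken28"`, the 28 chicken autosomes of at
#' least 1 Mb (up to ~198 Mb, with many micro-chromosomes), chosen because
#' the two genomes bracket the size-distribution regimes in which the
#' censoring/heteroscedasticity bias is mild (human) or severe (chicken).
#'
#' @param name `"human22"` or `"chicken28"`.
#' @return A `data.frame` of class `"genome_preset"` with columns `chrom`
#'   and `size_bp`, and attribute `name`.
#' @examples
#' g <- load_genome_preset("chicken28")
#' nrow(g)       # 28
#' range(g$size_bp) / 1e6
#' @export
load_genome_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.genome_presets)) {
    stop("unknown genome preset '", paste(name, collapse = ","),
         "'; available presets: ",
         paste(names(.genome_presets), collapse = ", "), call. = FALSE)
  }
  g <- .genome_presets[[name]]
  attr(g, "name") <- name
  class(g) <- c("genome_preset", "data.frame")
  g
}

# Accept a preset, a preset name, or a custom data.frame(chrom, size_bp).
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1) {
    return(load_genome_preset(genome))
  }
  if (!is.data.frame(genome) || !all(c("chrom", "size_bp") %in% names(genome))) {
    stop("genome must be a preset name or a data.frame with columns ",
         "'chrom' and 'size_bp'", call. = FALSE)
  }
  if (any(genome$size_bp <= 0)) {
    stop("validation error: non-positive chromosome length", call. = FALSE)
  }
  if (anyDuplicated(genome$chrom)) {
    stop("validation error: duplicated chromosome labels in genome", call. = FALSE)
  }
  genome
}
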