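#' @keywords internal
"_PACKAGE"

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)
GRADE_LEVELS <- c("1a", "1b", "2a", "2b", "2b->3")

#' Normalize chromosome tokens
#'
#' Accepts tokens with or without a leading `"chr"` prefix and returns the
#' bare token (`"1"`..`"22"`, `"X"`, `"Y"`). Unknown tokens raise an error.
#'
#' @param x character vector of chromosome tokens.
#' @return character vector of bare chromosome tokens.
#' @export
normalize_chrom <- function(x) {
  out <- sub("^chr", "", as.character(x))
  bad <- !(out %in% CHROM_LEVELS) & !is.na(out)
  if (any(bad)) {
    stop("unknown chromosome token(s): ", paste(unique(out[bad]), collapse = ", "))
  }
  out
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific sub-seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chromosome geometry used by the simulator
#'
#' Synthetic approximation of human chromosome sizes and centromere
#' positions (megabases), used to place genes and copy-number probes and to
#' assign p/q arms. These are rounded reference-genome figures, not exact
#' build coordinates; the pipeline itself never depends on them (annotation
#' is always an input), only the generator does.
#'
#' @return data.frame with columns `chromosome`, `length_mb`, `centromere_mb`.
#' @export
chrom_geometry <- function() {
  data.frame(
    chromosome = CHROM_LEVELS,
    length_mb = c(248, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
                  114, 107, 102, 90, 83, 80, 59, 64, 47, 51, 156, 57),
    centromere_mb = c(123, 93, 91, 50, 48, 60, 60, 45, 43, 40, 53, 36,
                      18, 17, 19, 37, 25, 18, 26, 28, 12, 15, 61, 10),
    stringsAsFactors = FALSE
  )
}

# Approximate per-chromosome known-gene counts (protein-coding scale),
# the generator's default annotation complement. Configurable per run.
default_gene_counts <- function() {
  stats::setNames(
    c(2000, 1200, 1050, 750, 850, 1000, 900, 650, 780, 730, 1300, 1000,
      320, 600, 600, 800, 1150, 270, 1400, 540, 230, 440, 850, 60),
    CHROM_LEVELS
  )
}

# arm of a position given chromosome geometry
position_arm <- function(chromosome, position, geometry = chrom_geometry()) {
  cen <- geometry$centromere_mb[match(chromosome, geometry$chromosome)] * 1e6
  ifelse(position <= cen, "p", "q")
}
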