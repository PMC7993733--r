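#' Default age-to-methylation functions for the panel
#'
#' Builds one age-response function per target CpG, parameterising how each
#' marker's methylation moves across the lifespan (ages 1-93). Directions
#' follow the markers' known behaviour: ELOVL2 hypermethylates with a
#' saturating power-law trajectory (the marker whose non-linearity motivates
#' power transformation before modelling); FHL2, TRIM59, PDE4C and KLF14
#' hypermethylate linearly, KLF14 with the smallest lifespan span;
#' MIR29B2CHG, EDARADD and ASPA hypomethylate. In bone, MIR29B2CHG C2/C3 are
#' flat (age-uncorrelated). Exact parameter values are the package's own
#' calibration, chosen to give lifespan spans of roughly 50-70 percent for
#' the wide-range markers and ~10 percent for KLF14.
#'
#' @param panel A `panel_definition`.
#' @param tissue One of `"blood"`, `"buccal"`, `"bone"`.
#' @param bio_sd Between-individual biological noise SD in percent.
#' @return A data frame (one row per CpG) with columns `cpg_id`, `marker`,
#'   `label`, `form` (linear/power), `intercept`, `slope`, `scale`,
#'   `exponent`, `direction` (hyper/hypo), `bio_sd`.
#' @export
default_age_functions <- function(panel, tissue = c("blood", "buccal", "bone"),
                                  bio_sd = 2.0) {
  tissue <- match.arg(tissue)
  base <- list(
    ELOVL2     = list(form = "power",  scale = 3.1,  exponent = 0.7,
                      intercept = 0,  slope = 0,     direction = "hyper"),
    FHL2       = list(form = "linear", intercept = 10, slope = 0.55,
                      scale = 0, exponent = 1, direction = "hyper"),
    TRIM59     = list(form = "linear", intercept = 8,  slope = 0.50,
                      scale = 0, exponent = 1, direction = "hyper"),
    PDE4C      = list(form = "linear", intercept = 12, slope = 0.65,
                      scale = 0, exponent = 1, direction = "hyper"),
    KLF14      = list(form = "linear", intercept = 4,  slope = 0.12,
                      scale = 0, exponent = 1, direction = "hyper"),
    MIR29B2CHG = list(form = "linear", intercept = 70, slope = -0.60,
                      scale = 0, exponent = 1, direction = "hypo"),
    EDARADD    = list(form = "linear", intercept = 65, slope = -0.35,
                      scale = 0, exponent = 1, direction = "hypo"),
    ASPA       = list(form = "linear", intercept = 55, slope = -0.30,
                      scale = 0, exponent = 1, direction = "hypo"))
  rows <- lapply(seq_len(nrow(panel$cpgs)), function(i) {
    cp <- panel$cpgs[i, ]
    b <- base[[cp$marker]]
    if (is.null(b)) stopf("no default age function for marker %s", cp$marker)
    # deterministic within-marker jitter so CpGs of one marker are not
    # perfectly collinear even before noise
    k <- as.integer(sub("^C", "", cp$label))
    jit <- 1 + 0.03 * (k - 1)
    slope <- b$slope * jit
    scale <- b$scale * jit
    if (tissue == "bone" && cp$marker == "MIR29B2CHG" && cp$label %in% c("C2", "C3")) {
      slope <- 0
    }
    data.frame(cpg_id = cp$cpg_id, marker = cp$marker, label = cp$label,
               form = b$form, intercept = b$intercept, slope = slope,
               scale = scale, exponent = b$exponent, direction = b$direction,
               bio_sd = bio_sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' True per-CpG methylation for a given age
#'
#' Evaluates the age-response function of every CpG at one age, optionally
#' adds between-individual biological noise, and clamps to \[0, 100\]
#' percent. Linear form: `intercept + slope * age`. Power form:
#' `scale * age^exponent` for hypermethylating CpGs,
#' `100 - scale * age^exponent` for hypomethylating ones.
#'
#' @param age Age in years (scalar, >= 0).
#' @param functions Data frame as returned by [default_age_functions()].
#' @param noise If `FALSE`, return the noise-free curve values.
#' @param seed Optional RNG seed.
#' @return Named numeric vector of percent methylation (names = `cpg_id`).
#' @export
true_methylation <- function(age, functions, noise = TRUE, seed = NULL) {
  stopifnot(length(age) == 1L, is.numeric(age), age >= 0)
  f <- functions
  mu <- ifelse(f$form == "linear",
               f$intercept + f$slope * age,
               ifelse(f$direction == "hyper",
                      f$scale * age^f$exponent,
                      100 - f$scale * age^f$exponent))
  with_seed(seed, {
    if (noise) mu <- mu + stats::rnorm(length(mu), 0, f$bio_sd)
    out <- clamp(mu)
    names(out) <- f$cpg_id
    out
  })
}
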