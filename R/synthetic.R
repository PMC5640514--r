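# Seeded generators emulating the statistical structure of the two data
# types the pipelines consume: nucleus-centroid tables along a myotube axis
# (clustered vs dispersed vs uniform) and BioID/TMT reporter tables with
# sample-to-sample bait variation, background binders and a planted
# myotube-enriched interactor set.

#' Generate synthetic myotube nucleus tables
#'
#' Draws axial nucleus positions per myotube under one of three regimes:
#' `"clustered"` (positions ~ Normal(L/2, cluster_sd), truncated to the
#' myotube), `"dispersed"` (even spacing spanning the myotube plus Gaussian
#' jitter), `"uniform"` (i.i.d. Uniform(0, L)). Myotube length follows the
#' 19 um-per-nucleus rule by default. Truth labels (regime, counts) are
#' returned alongside the data.
#'
#' @param regime `"clustered"`, `"dispersed"` or `"uniform"`.
#' @param n_myotubes Number of myotubes.
#' @param nuclei_range Integer range of nuclei per myotube (inclusive),
#'   sampled uniformly.
#' @param length_per_nucleus Myotube length per nucleus, um.
#' @param cluster_sd Cluster width sigma, um (> 0; clustered regime).
#' @param jitter_sd Jitter sigma, um (>= 0; dispersed regime).
#' @param seed Optional integer seed.
#' @return List with `nuclei` (data.frame `myotube_id`, `length_um`,
#'   `x_um`) and `truth` (per-myotube regime and nucleus count).
#' @export
#' @examples
#' g <- gen_nuclei("dispersed", n_myotubes = 3, jitter_sd = 0, seed = 1)
#' sf_table(g$nuclei)$sf  # all exactly 1
gen_nuclei <- function(regime = c("clustered", "dispersed", "uniform"),
                       n_myotubes = 50,
                       nuclei_range = c(5, 9),
                       length_per_nucleus = 19,
                       cluster_sd = 5,
                       jitter_sd = 1,
                       seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_myotubes >= 1, length(nuclei_range) == 2,
            nuclei_range[1] >= 3, nuclei_range[2] >= nuclei_range[1],
            length_per_nucleus > 0, jitter_sd >= 0)
  if (regime == "clustered" && cluster_sd <= 0)
    stop("cluster_sd must be > 0 in the clustered regime")
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); truth <- list()
  for (i in seq_len(n_myotubes)) {
    n <- sample(seq(nuclei_range[1], nuclei_range[2]), 1)
    L <- length_per_nucleus * n
    x <- switch(regime,
      clustered = {
        # inverse-CDF truncated normal on [0, L]
        lo <- stats::pnorm((0 - L / 2) / cluster_sd)
        hi <- stats::pnorm((L - L / 2) / cluster_sd)
        L / 2 + cluster_sd * qnorm(runif(n, lo, hi))
      },
      dispersed = pmin(pmax(seq(0, L, length.out = n) +
                              rnorm(n, 0, jitter_sd), 0), L),
      uniform = runif(n, 0, L))
    id <- sprintf("mt%04d", i)
    rows[[i]] <- data.frame(myotube_id = id, length_um = L, x_um = x,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(myotube_id = id, regime = regime, n_nuclei = n,
                             length_um = L, stringsAsFactors = FALSE)
  }
  list(nuclei = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a synthetic BioID/TMT quantification table
#'
#' Emulates the structure of a bait-normalizable TMT experiment: background
#' proteins whose expected +DOX/-DOX ratio is the same in myoblasts and
#' myotubes, a planted subset whose myotube ratio is multiplied by
#' `effect_size`, per-sample bait expression scales applied to whole +DOX
#' columns, multiplicative log-normal measurement noise at the stated CV,
#' and optional missingness. The planted set is disjoint from the
#' background and returned as the truth table.
#'
#' @param n_proteins Number of non-bait proteins.
#' @param n_planted Number of planted myotube-enriched interactors.
#' @param effect_size Fold enrichment of planted proteins in myotubes (> 0).
#' @param abundance_meanlog,abundance_sdlog Log-normal baseline abundance
#'   parameters.
#' @param background_labeling Expected +DOX/-DOX ratio of background
#'   binders (identical in both cell states).
#' @param bait_scale_sdlog Log-SD of the per-(+DOX)-sample bait expression
#'   scale factors.
#' @param cv Measurement coefficient of variation (0 = noiseless).
#' @param missing_rate Probability that a non-bait measurement is missing.
#' @param n_replicates Biological replicates per cell state.
#' @param bait_abundance Raw bait reporter abundance scale.
#' @param seed Optional integer seed.
#' @return List with `table` (a [quant_table()]), `truth` (data.frame
#'   `protein`, `planted`), and `bait_scales` (the per-sample scales
#'   actually applied).
#' @export
#' @examples
#' g <- gen_tmt(n_proteins = 100, n_planted = 10, cv = 0, seed = 1)
#' res <- bioid_pipeline(g$table)
#' all(res$result$protein[res$result$pass] %in%
#'     g$truth$protein[g$truth$planted])
gen_tmt <- function(n_proteins = 1000,
                    n_planted = 50,
                    effect_size = 4,
                    abundance_meanlog = log(1000),
                    abundance_sdlog = 1,
                    background_labeling = 3,
                    bait_scale_sdlog = 0.3,
                    cv = 0.2,
                    missing_rate = 0,
                    n_replicates = 3,
                    bait_abundance = 1e5,
                    seed = NULL) {
  stopifnot(n_proteins >= 1, n_planted >= 0, n_planted <= n_proteins,
            cv >= 0, missing_rate >= 0, missing_rate < 1, n_replicates >= 1)
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (!is.null(seed)) set.seed(seed)

  proteins <- sprintf("prot%04d", seq_len(n_proteins))
  planted <- if (n_planted > 0) sample(proteins, n_planted) else character(0)
  bait <- "BAIT_BirA"
  states <- c("myoblast", "myotube")
  treatments <- c("noDOX_noBiotin", "noDOX_biotin", "DOX_biotin")
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         treatment = treatments, cell_state = states,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- with(samples, paste(cell_state, treatment,
                                           paste0("r", replicate), sep = "_"))

  base <- rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
  sdl <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(n) if (sdl > 0) rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n)

  n_dox <- sum(samples$treatment == "DOX_biotin")
  bait_scales <- setNames(rlnorm(n_dox, 0, bait_scale_sdlog),
                          samples$sample_id[samples$treatment == "DOX_biotin"])

  ab <- matrix(NA_real_, n_proteins + 1L, nrow(samples),
               dimnames = list(c(proteins, bait), samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    trt <- samples$treatment[j]; st <- samples$cell_state[j]
    if (trt == "DOX_biotin") {
      eff <- ifelse(proteins %in% planted & st == "myotube", effect_size, 1)
      sc <- bait_scales[samples$sample_id[j]]
      ab[proteins, j] <- base * background_labeling * eff * sc *
        noise(n_proteins)
      ab[bait, j] <- bait_abundance * sc * noise(1)
    } else {
      ab[proteins, j] <- base * noise(n_proteins)
      ab[bait, j] <- bait_abundance * 1e-3 * noise(1)  # leak-level bait
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(n_proteins * nrow(samples)) < missing_rate,
                   n_proteins, nrow(samples))
    ab[proteins, ][drop] <- NA_real_
  }
  list(table = quant_table(ab, samples, bait),
       truth = data.frame(protein = proteins,
                          planted = proteins %in% planted,
                          stringsAsFactors = FALSE),
       bait_scales = bait_scales)
}

#' Write / read nucleus tables
#'
#' Plain tab-delimited text in the schema consumed by [sf_table()].
#'
#' @param nuclei Data.frame (`myotube_id`, `length_um`, `x_um`).
#' @param file Path.
#' @return `write_nuclei`: the path, invisibly. `read_nuclei`: the
#'   data.frame.
#' @export
write_nuclei <- function(nuclei, file) {
  utils::write.table(nuclei, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_nuclei
#' @export
read_nuclei <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
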