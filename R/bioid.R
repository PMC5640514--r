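#' Construct a BioID/TMT quantification table
#'
#' Container for protein-level reporter abundances across the BioID design:
#' two cell states (myoblast, myotube) x three treatments (untreated
#' `noDOX_noBiotin`, biotin-only `noDOX_biotin`, induced `DOX_biotin`) x
#' replicates. Abundances are arbitrary units >= 0; missing values are `NA`
#' (never imputed silently). One row is flagged as the bait (the
#' BirA*-tagged protein), whose per-sample signal carries the correcting
#' factors for [bait_normalize()].
#'
#' @param abundance Numeric matrix, proteins x samples, with protein ids as
#'   rownames and sample ids as colnames.
#' @param samples Data.frame with one row per column of `abundance`:
#'   `sample_id`, `cell_state` (`"myoblast"`/`"myotube"`), `treatment`
#'   (`"noDOX_noBiotin"`/`"noDOX_biotin"`/`"DOX_biotin"`), `replicate`.
#' @param bait Protein id of the bait row.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(abundance, samples, bait) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance))) stop("abundance needs protein rownames")
  need <- c("sample_id", "cell_state", "treatment", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "))
  if (nrow(samples) != ncol(abundance))
    stop("samples must have one row per abundance column")
  if (is.null(colnames(abundance))) colnames(abundance) <- samples$sample_id
  if (!all(samples$cell_state %in% c("myoblast", "myotube")))
    stop("cell_state must be 'myoblast' or 'myotube'")
  if (!all(samples$treatment %in%
           c("noDOX_noBiotin", "noDOX_biotin", "DOX_biotin")))
    stop("unknown treatment level")
  if (!bait %in% rownames(abundance))
    stop("bait '", bait, "' not found among protein ids")
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be >= 0")
  structure(list(abundance = abundance, samples = samples, bait = bait,
                 normalized = FALSE, factors = NULL),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d proteins x %d samples, bait '%s'%s\n",
              nrow(x$abundance), ncol(x$abundance), x$bait,
              if (x$normalized) ", bait-normalized" else ""))
  invisible(x)
}

#' Bait-derived normalization of a quantification table
#'
#' Bait (BirA*-fusion) expression varies from sample to sample; since all
#' labeling is bait-dependent, induced (+DOX) columns are made comparable by
#' scaling each so that the bait abundance equals the geometric mean of the
#' bait abundances across +DOX samples. The per-sample correcting factors
#' are recorded in the result. Control (-DOX) columns, where the bait is not
#' expressed, are left unscaled.
#'
#' @param table A [quant_table()].
#' @return The normalized `quant_table`, with `factors` (named per-sample
#'   multipliers) and `normalized = TRUE`.
#' @export
#' @examples
#' tt <- gen_tmt(n_proteins = 20, seed = 1)
#' norm <- bait_normalize(tt$table)
#' norm$factors
bait_normalize <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  dox <- which(table$samples$treatment == "DOX_biotin")
  if (length(dox) == 0) stop("no +DOX samples present")
  bait_ab <- table$abundance[table$bait, dox]
  bad <- which(is.na(bait_ab) | bait_ab <= 0)
  if (length(bad))
    stop("bait abundance missing or zero in +DOX sample(s): ",
         paste(table$samples$sample_id[dox][bad], collapse = ", "))
  ref <- exp(mean(log(bait_ab)))
  factors <- setNames(rep(1, ncol(table$abundance)),
                      colnames(table$abundance))
  factors[dox] <- ref / bait_ab
  out <- table
  out$abundance <- sweep(table$abundance, 2, factors, `*`)
  out$factors <- factors
  out$normalized <- TRUE
  out
}

# pick, per cell state and replicate, the -DOX control column: biotin-only
# when present, untreated otherwise
.control_column <- function(samples, cell_state, replicate) {
  cand <- which(samples$cell_state == cell_state &
                  samples$replicate == replicate &
                  samples$treatment == "noDOX_biotin")
  if (!length(cand))
    cand <- which(samples$cell_state == cell_state &
                    samples$replicate == replicate &
                    samples$treatment == "noDOX_noBiotin")
  if (!length(cand)) NA_integer_ else cand[1]
}

#' Induced / control abundance ratios
#'
#' For every protein, cell state, and replicate, computes the ratio of the
#' abundance in doxycycline-induced cells (+DOX +biotin) to the abundance in
#' untreated control cells (-DOX). The biotin-only control (-DOX +biotin) is
#' used as denominator when present, else the fully untreated control. Zero
#' or missing denominators are handled by a pseudocount (default: smallest
#' nonzero abundance in the denominator column); affected ratios are
#' flagged. Proteins missing in the numerator yield `NA` ratios, flagged,
#' not an error.
#'
#' @param table A [quant_table()], normally after [bait_normalize()].
#' @param pseudocount `"auto"` (per-column smallest nonzero abundance) or a
#'   numeric value added to the denominator.
#' @return Data.frame with columns `protein`, `cell_state`, `replicate`,
#'   `ratio`, `flag` (`""`, `"missing_numerator"`, `"pseudocount_denominator"`).
#' @export
dox_ratios <- function(table, pseudocount = "auto") {
  stopifnot(inherits(table, "quant_table"))
  s <- table$samples
  dox <- which(s$treatment == "DOX_biotin")
  rows <- list()
  for (j in dox) {
    ctrl <- .control_column(s, s$cell_state[j], s$replicate[j])
    if (is.na(ctrl))
      stop("no -DOX control sample for ", s$cell_state[j], " replicate ",
           s$replicate[j])
    num <- table$abundance[, j]
    den <- table$abundance[, ctrl]
    pc <- if (identical(pseudocount, "auto")) {
      nz <- den[!is.na(den) & den > 0]
      if (length(nz)) min(nz) else 1
    } else as.numeric(pseudocount)
    den_eff <- ifelse(is.na(den), 0, den)
    used_pc <- is.na(den) | den <= 0
    ratio <- num / (den_eff + pc)
    flag <- ifelse(is.na(num), "missing_numerator",
                   ifelse(used_pc, "pseudocount_denominator", ""))
    rows[[length(rows) + 1L]] <- data.frame(
      protein = rownames(table$abundance),
      cell_state = s$cell_state[j], replicate = s$replicate[j],
      ratio = ratio, flag = flag,
      pseudocount = pc, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-replicate enrichment records
#'
#' Joins the myoblast and myotube +DOX/-DOX ratios per protein and
#' replicate into the record format consumed by [enrichment_filter()].
#'
#' @param ratios Output of [dox_ratios()].
#' @return Data.frame with columns `protein`, `replicate`, `r_mb`
#'   (myoblast ratio), `r_mt` (myotube ratio).
#' @export
enrichment_records <- function(ratios) {
  mb <- ratios[ratios$cell_state == "myoblast",
               c("protein", "replicate", "ratio")]
  mt <- ratios[ratios$cell_state == "myotube",
               c("protein", "replicate", "ratio")]
  names(mb)[3] <- "r_mb"; names(mt)[3] <- "r_mt"
  merge(mb, mt, by = c("protein", "replicate"))
}

#' Replicate-consistent myotube-enrichment filter
#'
#' A protein is called enriched in a replicate when its myotube ratio
#' strictly exceeds its myoblast ratio by the fold threshold
#' (`r_mt / r_mb > fold_threshold`, with a 1e-9 relative guard so that
#' floating-point ties at the threshold never count), and passes overall
#' when enriched in at least two of three replicates. With fewer than three available
#' replicates the protein is still evaluated (flagged), but at least two
#' enriched replicates are always required to pass. The pass set is ordered
#' by median fold change, descending.
#'
#' @param records Data.frame from [enrichment_records()] (`protein`,
#'   `replicate`, `r_mb`, `r_mt`).
#' @param fold_threshold Minimal myotube/myoblast fold change per replicate.
#'   The default of 2 sits at the log-scale midpoint between a null fold of
#'   1 and a 4-fold interactor effect: with symmetric multiplicative noise a
#'   threshold of exactly 1 would pass half of the background by
#'   construction (each replicate is a fair coin), so a margin is required
#'   for the filter to have any specificity. Use `fold_threshold = 1` for
#'   the permissive "any preferential association" reading.
#' @return Data.frame, one row per protein: `protein`, `n_replicates`,
#'   `n_enriched`, `median_fold`, `pass`, `flag`; pass rows first, ordered
#'   by `median_fold` descending.
#' @export
#' @examples
#' rec <- data.frame(protein = "p1", replicate = 1:3,
#'                   r_mb = c(1, 1, 2), r_mt = c(2, 3, 1))
#' enrichment_filter(rec, fold_threshold = 1)  # enriched in 2 of 3: pass
enrichment_filter <- function(records, fold_threshold = 2) {
  stopifnot(all(c("protein", "replicate", "r_mb", "r_mt") %in%
                  names(records)),
            fold_threshold > 0)
  prot <- unique(records$protein)
  out <- do.call(rbind, lapply(prot, function(p) {
    sub <- records[records$protein == p & !is.na(records$r_mb) &
                     !is.na(records$r_mt) & records$r_mb > 0, ]
    fold <- sub$r_mt / sub$r_mb
    n_rep <- nrow(sub)
    n_enr <- sum(fold > fold_threshold * (1 + 1e-9))
    data.frame(protein = p, n_replicates = n_rep, n_enriched = n_enr,
               median_fold = if (n_rep) median(fold) else NA_real_,
               pass = n_enr >= 2,
               flag = if (n_rep < 3) "fewer_than_3_replicates" else "",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$pass, -out$median_fold), ]
  rownames(out) <- NULL
  out
}

#' Identification gate
#'
#' Upstream of enrichment, only proteins identified in at least two
#' biological replicates are analyzed.
#'
#' @param flags Logical matrix (proteins x replicates) or data.frame of
#'   identification calls, protein ids as rownames.
#' @param min_replicates Minimal number of replicates (default 2).
#' @return Character vector of retained protein ids.
#' @export
#' @examples
#' m <- rbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, FALSE, FALSE))
#' identification_gate(m)  # "a"
identification_gate <- function(flags, min_replicates = 2) {
  m <- as.matrix(flags)
  if (is.null(rownames(m))) stop("flags need protein rownames")
  keep <- rowSums(m, na.rm = TRUE) >= min_replicates
  rownames(m)[keep]
}

#' Threshold sweep of the enrichment filter
#'
#' Reports the size of the pass set as a function of the per-replicate fold
#' threshold. Useful for locating the cutoff behind a published candidate
#' count when the original threshold is not documented: the pass-set size is
#' monotonically non-increasing in the threshold, so the sweep brackets any
#' attainable count.
#'
#' @param records Data.frame from [enrichment_records()].
#' @param thresholds Numeric vector of fold thresholds.
#' @return Data.frame: `threshold`, `n_pass`.
#' @export
enrichment_threshold_sweep <- function(records,
                                       thresholds = c(1, 1.2, 1.5, 2, 3, 4)) {
  data.frame(
    threshold = thresholds,
    n_pass = vapply(thresholds, function(th)
      sum(enrichment_filter(records, fold_threshold = th)$pass), 0L))
}

#' Run the full BioID quantitation pipeline
#'
#' Identification gate, bait normalization, +DOX/-DOX ratios, and the
#' replicate-consistent enrichment filter, in order.
#'
#' @param table A [quant_table()].
#' @param fold_threshold Passed to [enrichment_filter()].
#' @param identified Optional logical matrix for [identification_gate()];
#'   by default every protein quantified (non-NA +DOX abundance) in a
#'   replicate counts as identified there.
#' @return List with `normalized` (the normalized table), `ratios`,
#'   `records`, and `result` (the [enrichment_filter()] output; bait row
#'   excluded).
#' @export
bioid_pipeline <- function(table, fold_threshold = 2, identified = NULL) {
  stopifnot(inherits(table, "quant_table"))
  if (is.null(identified)) {
    dox <- which(table$samples$treatment == "DOX_biotin" &
                   table$samples$cell_state == "myotube")
    identified <- !is.na(table$abundance[, dox, drop = FALSE])
  }
  keep <- identification_gate(identified)
  norm <- bait_normalize(table)
  ratios <- dox_ratios(norm)
  ratios <- ratios[ratios$protein %in% keep & ratios$protein != table$bait, ]
  records <- enrichment_records(ratios)
  list(normalized = norm, ratios = ratios, records = records,
       result = enrichment_filter(records, fold_threshold))
}

#' Read / write quantification tables as delimited text
#'
#' Tab-delimited schema: one `protein` column, then one column per sample
#' named `<cell_state>.<treatment>.r<replicate>` (for example
#' `myotube.DOX_biotin.r2`). Externally produced protein-level tables
#' exported to this schema can be fed straight into [bioid_pipeline()].
#'
#' @param table A [quant_table()].
#' @param file Path.
#' @param bait Bait protein id (for `read_quant_table`).
#' @return `write_quant_table`: the path, invisibly. `read_quant_table`:
#'   a `quant_table`.
#' @export
write_quant_table <- function(table, file) {
  stopifnot(inherits(table, "quant_table"))
  s <- table$samples
  cn <- paste0(s$cell_state, ".", s$treatment, ".r", s$replicate)
  df <- data.frame(protein = rownames(table$abundance),
                   table$abundance, check.names = FALSE)
  names(df) <- c("protein", cn)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(file, bait) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "protein") stop("first column must be 'protein'")
  parts <- strsplit(names(df)[-1], ".", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3
  if (any(bad))
    stop("sample columns must be named <cell_state>.<treatment>.r<replicate>")
  samples <- data.frame(
    sample_id = names(df)[-1],
    cell_state = vapply(parts, `[`, "", 1),
    treatment = vapply(parts, `[`, "", 2),
    replicate = as.integer(sub("^r", "", vapply(parts, `[`, "", 3))),
    stringsAsFactors = FALSE)
  ab <- as.matrix(df[, -1, drop = FALSE])
  rownames(ab) <- df$protein
  quant_table(ab, samples, bait)
}
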