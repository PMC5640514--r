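#' Even-spacing reference distance
#'
#' Mean of all unordered pairwise distances between `n` points evenly spaced
#' from 0 to `L`: `L * (n + 1) / (3 * (n - 1))`. This is the reference
#' ("maximal theoretical") average internuclear distance against which the
#' observed average is normalized.
#'
#' @param n Number of nuclei (>= 2).
#' @param L Myotube length, um.
#' @return Reference mean pairwise distance, um.
#' @export
spreading_reference <- function(n, L) {
  stopifnot(n >= 2, L > 0)
  L * (n + 1) / (3 * (n - 1))
}

#' Nuclear spreading factor
#'
#' Ratio between the observed and the reference average distance between
#' nuclei along the myotube axis. The observed average is the mean over all
#' unordered pairs of `|x_i - x_j|`; the reference is the same mean for
#' nuclei evenly spaced over the full myotube length
#' ([spreading_reference()]). SF = 1 for perfectly even spacing spanning the
#' myotube, and approaches 0 as nuclei cluster. Only myotubes with at least
#' 3 nuclei are scored. A consecutive-neighbour variant of the observed mean
#' is available for sensitivity analysis.
#'
#' @param x Axial nucleus positions, um.
#' @param L Myotube length, um (> 0).
#' @param method `"pairwise"` (default) or `"consecutive"` (mean gap between
#'   sorted neighbours, normalized by the even-spacing gap `L / (n - 1)`).
#' @return The spreading factor (dimensionless, >= 0).
#' @export
#' @examples
#' spreading_factor(seq(0, 100, length.out = 5), 100)  # 1: even spacing
#' spreading_factor(c(0, 10, 20), 100)                 # 0.2
spreading_factor <- function(x, L, method = c("pairwise", "consecutive")) {
  method <- match.arg(method)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("myotube length L must be a positive number")
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3)
    stop("spreading factor requires at least 3 nuclei (got ", n, ")")
  if (method == "pairwise") {
    obs <- mean(stats::dist(matrix(x, ncol = 1)))
    obs / spreading_reference(n, L)
  } else {
    mean(diff(sort(x))) / (L / (n - 1))
  }
}

#' Spreading factors for a table of myotubes
#'
#' Applies [spreading_factor()] per myotube to a long-format nucleus table
#' (the schema written by [gen_nuclei()] and [run_ensemble()]). Myotubes
#' with fewer than 3 nuclei are excluded; the exclusions and their reasons
#' are attached as attribute `"excluded"`.
#'
#' @param nuclei Data.frame with columns `myotube_id`, `length_um`, `x_um`
#'   (one row per nucleus).
#' @param method Passed to [spreading_factor()].
#' @return Data.frame with one row per included myotube: `myotube_id`,
#'   `length_um`, `n_nuclei`, `sf`.
#' @export
sf_table <- function(nuclei, method = "pairwise") {
  need <- c("myotube_id", "length_um", "x_um")
  if (!all(need %in% names(nuclei)))
    stop("nuclei table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(nuclei$myotube_id)
  rows <- list(); excl <- list()
  for (id in ids) {
    sub <- nuclei[nuclei$myotube_id == id, ]
    L <- sub$length_um[1]
    if (nrow(sub) < 3) {
      excl[[length(excl) + 1L]] <- data.frame(
        myotube_id = id, reason = sprintf("only %d nuclei (< 3)", nrow(sub)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      myotube_id = id, length_um = L, n_nuclei = nrow(sub),
      sf = spreading_factor(sub$x_um, L, method = method))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(myotube_id = character(0), length_um = numeric(0),
               n_nuclei = integer(0), sf = numeric(0))
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two groups of
#' spreading factors (or any numeric samples). The U statistic uses midranks
#' for ties. P-values come from exact enumeration when the smaller group has
#' at most 8 observations and there are no ties, and otherwise from the
#' normal approximation with tie correction and continuity correction
#' (delegated to [stats::wilcox.test()] configured accordingly).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (the Mann-Whitney U for `a` over `b`), `p`
#'   (two-sided), `exact` (logical) and `n` (group sizes).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, two-sided p = 0.1
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, conf.int = FALSE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact,
       n = c(length(a), length(b)))
}

#' Compare spreading-factor groups
#'
#' Summarizes each group (mean, interquartile range, n) and tests all pairs
#' of groups with the two-sided Mann-Whitney test.
#'
#' @param sf Either an `ensemble_result` from [run_ensemble()] or a
#'   data.frame with columns `sf` and a grouping column.
#' @param group Name of the grouping column (default `"condition"`).
#' @return An object of class `sf_comparison`: list with `groups` (per-group
#'   summary) and `tests` (pairwise U and p).
#' @export
compare_conditions <- function(sf, group = "condition") {
  if (inherits(sf, "ensemble_result")) sf <- sf$sf
  if (!all(c("sf", group) %in% names(sf)))
    stop("need columns 'sf' and '", group, "'")
  g <- as.character(sf[[group]])
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups to compare")
  groups <- do.call(rbind, lapply(lev, function(lv) {
    v <- sf$sf[g == lv]
    data.frame(group = lv, n = length(v), mean = mean(v),
               q25 = unname(quantile(v, 0.25)),
               q75 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(lev, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    va <- sf$sf[g == pairs[1, i]]; vb <- sf$sf[g == pairs[2, i]]
    mw <- mann_whitney(va, vb)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               U = mw$U, p = mw$p, exact = mw$exact,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, tests = tests), class = "sf_comparison")
}

#' @export
print.sf_comparison <- function(x, ...) {
  cat("Spreading-factor comparison\n\nGroup summaries:\n")
  print(transform(x$groups, mean = round(mean, 3), q25 = round(q25, 3),
                  q75 = round(q75, 3)), row.names = FALSE)
  cat("\nPairwise two-sided Mann-Whitney tests:\n")
  print(transform(x$tests, p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Write a comparison report
#'
#' Writes the group summary and pairwise tests of [compare_conditions()] as
#' tab-delimited text.
#'
#' @param comparison An `sf_comparison`.
#' @param file Output path; `"-"` prints to the console.
#' @return The file path, invisibly.
#' @export
write_sf_report <- function(comparison, file) {
  stopifnot(inherits(comparison, "sf_comparison"))
  con <- if (identical(file, "-")) stdout() else file
  lines <- c("# group summaries",
             paste(capture_tsv(comparison$groups), collapse = "\n"),
             "# pairwise Mann-Whitney",
             paste(capture_tsv(comparison$tests), collapse = "\n"))
  writeLines(lines, con)
  invisible(file)
}

capture_tsv <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1, function(r) paste(r, collapse = "\t")))
}
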