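#' Ranked virtual-screening library
#'
#' An ordered screening result: one row per compound with its docking score
#' (affinity units; lower = stronger predicted binding) and its benchmark
#' label (active or decoy). Entries are sorted ascending by score, best
#' first; tied scores keep their input order (stable sort).
#'
#' @param id compound identifiers.
#' @param score numeric docking scores (lower is better).
#' @param label \code{"active"} or \code{"decoy"} per compound.
#' @return A data frame of class \code{ranked_library} with columns
#'   \code{id}, \code{score}, \code{label}, sorted by score.
#' @export
ranked_library <- function(id, score, label) {
  score <- as.numeric(score)
  label <- as.character(label)
  if (!all(label %in% c("active", "decoy")))
    stop("labels must be 'active' or 'decoy'")
  if (length(id) != length(score) || length(id) != length(label))
    stop("id, score and label must have equal length")
  if (length(score) < 1L) stop("empty library")
  if (!all(is.finite(score))) stop("scores must be finite")
  ord <- order(score)  # stable: ties keep input order
  structure(data.frame(id = as.character(id)[ord], score = score[ord],
                       label = label[ord], stringsAsFactors = FALSE),
            class = c("ranked_library", "data.frame"))
}

#' @rdname ranked_library
#' @param path delimited file (TSV/CSV/whitespace) with a header line and
#'   columns \code{id}, \code{score}, \code{label}.
#' @param sep field separator passed to \code{read.table}; the default
#'   \code{""} accepts any whitespace.
#' @export
read_ranked_library <- function(path, sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "score", "label"), names(tab))
  if (length(miss)) stop("ranked-results table missing columns: ",
                         paste(miss, collapse = ", "))
  ranked_library(tab$id, tab$score, tab$label)
}

check_two_classes <- function(lib) {
  stopifnot(inherits(lib, "ranked_library"))
  n_act <- sum(lib$label == "active")
  if (n_act == 0L) stop("library contains no actives")
  if (n_act == nrow(lib)) stop("library contains no decoys")
  invisible(n_act)
}

#' Enrichment factor
#'
#' Ratio of the concentration of actives in the top fraction of the ranked
#' library to their concentration in the whole library:
#' \code{(actives_in_top / top_size) / (n_actives / N)} with
#' \code{top_size = ceiling(top_fraction * N)} (at least 1). 1.0 is the
#' random-ranking expectation; the maximum is \code{N / n_actives} (capped
#' by the top size).
#'
#' @param lib a [ranked_library].
#' @param top_fraction fraction of the library examined, in (0, 1]; 0.01 and
#'   0.10 give the usual EF1\% and EF10\%.
#' @return Enrichment factor (>= 0).
#' @export
enrichment_factor <- function(lib, top_fraction) {
  stopifnot(inherits(lib, "ranked_library"))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  n_act <- sum(lib$label == "active")
  if (n_act == 0L) stop("library contains no actives")
  N <- nrow(lib)
  k <- max(1L, ceiling(top_fraction * N))
  hits <- sum(lib$label[seq_len(k)] == "active")
  (hits / k) / (n_act / N)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC: exponentially rank-weighted
#' enrichment mapped to [0, 1] via the robust initial enhancement (RIE)
#' normalization. With the conventional alpha = 20, about 80\% of the total
#' rank weight falls in the top 8\% of the library, so BEDROC20 rewards
#' early recognition of actives. Depends on ranks only, so it is invariant
#' to monotone transforms of the scores.
#'
#' @param lib a [ranked_library] with at least one active and one decoy.
#' @param alpha early-recognition exponent (> 0; default 20).
#' @return BEDROC in [0, 1].
#' @export
bedroc <- function(lib, alpha = 20) {
  n <- check_two_classes(lib)
  if (alpha <= 0) stop("alpha must be positive")
  N <- nrow(lib)
  Ra <- n / N
  r <- which(lib$label == "active")  # ranks of actives, 1 = best
  rie <- mean(exp(-alpha * r / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' @rdname bedroc
#' @details \code{bedroc_weight_fraction} reports the fraction of the total
#'   exponential rank weight carried by the top \code{top_fraction} of a
#'   library of \code{n} compounds — the quantity behind the "80\% of the
#'   enrichment from the top 8\%" reading of alpha = 20.
#' @param top_fraction top fraction of the library.
#' @param n library size used for the discrete sum.
#' @export
bedroc_weight_fraction <- function(alpha = 20, top_fraction = 0.08, n = 1e5) {
  r <- seq_len(n)
  w <- exp(-alpha * r / n)
  sum(w[r <= top_fraction * n]) / sum(w)
}

#' Enrichment AUC (rank-based)
#'
#' Area under the receiver-operating-characteristic-style enrichment curve,
#' computed by the rank-sum identity: the probability that a randomly chosen
#' active is ranked ahead of a randomly chosen decoy, with tied scores
#' contributing 1/2. Equals 1 for perfect ranking, 0.5 in expectation for a
#' random one.
#'
#' @param lib a [ranked_library].
#' @return AUC in [0, 1].
#' @export
enrichment_auc <- function(lib) {
  n_act <- check_two_classes(lib)
  n_dec <- nrow(lib) - n_act
  # midranks over scores; actives want *low* scores, i.e. low ranks
  rk <- rank(lib$score, ties.method = "average")
  r_act <- sum(rk[lib$label == "active"])
  u <- n_act * n_dec + n_act * (n_act + 1) / 2 - r_act
  u / (n_act * n_dec)
}

#' Top fraction of the library holding half of the actives
#'
#' ACT-50\%: the smallest top fraction k/N of the ranked library whose top k
#' compounds contain at least \code{ceiling(recovery * n_actives)} actives.
#' Smaller is better; 0.5 * (N + n_actives) / (N * n_actives)-ish values near
#' \code{recovery} indicate no enrichment.
#'
#' @param lib a [ranked_library].
#' @param recovery fraction of the actives to recover (default 0.5).
#' @return Fraction in (0, 1].
#' @export
act_fraction <- function(lib, recovery = 0.5) {
  stopifnot(inherits(lib, "ranked_library"))
  n_act <- sum(lib$label == "active")
  if (n_act == 0L) stop("library contains no actives")
  if (recovery <= 0 || recovery > 1) stop("recovery must be in (0, 1]")
  need <- ceiling(recovery * n_act)
  k <- which(cumsum(lib$label == "active") >= need)[1L]
  k / nrow(lib)
}

# exact two-sided p from a discrete statistic distribution:
# 2 * min(P(T <= t), P(T >= t)), capped at 1.
two_sided_from_tails <- function(values, probs, observed, tol = 1e-9) {
  lo <- sum(probs[values <= observed + tol])
  hi <- sum(probs[values >= observed - tol])
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sample nonparametric location test on ranks, used to compare score
#' distributions of actives and decoys. U is computed from midranks; the
#' two-sided p-value comes from exact enumeration of all rank assignments
#' when \code{length(a) + length(b) <= exact_max} (ties handled by
#' enumerating the observed midranks), otherwise from the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param a,b numeric samples.
#' @param exact_max combined size at or below which enumeration is used
#'   (default 12).
#' @return List with \code{U} (for sample \code{a}), \code{p} (two-sided)
#'   and \code{method}.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b), ties.method = "average")
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_max) {
    picks <- utils::combn(n, na)
    u_all <- colSums(matrix(rk[picks], nrow = na)) - na * (na + 1) / 2
    p <- two_sided_from_tails(u_all, rep(1 / ncol(picks), ncol(picks)), U)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(rk)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' One-sample nonparametric test on paired differences (e.g. per-target
#' metric differences between two docking protocols). Zero differences are
#' discarded; the positive-rank sum W uses midranks of the absolute
#' differences. Two-sided p by exact enumeration of all sign patterns when
#' the nonzero count is at most \code{exact_max}, else the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param diffs numeric paired differences.
#' @param exact_max nonzero-difference count at or below which enumeration
#'   is used (default 15).
#' @return List with \code{W} (positive-rank sum), \code{p}, \code{n_nonzero}
#'   and \code{method}.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 15L) {
  d <- as.numeric(diffs)
  d <- d[d != 0]
  if (length(d) < 1L)
    stop("all differences are zero; no difference to test")
  n <- length(d)
  rk <- rank(abs(d), ties.method = "average")
  W <- sum(rk[d > 0])
  if (n <= exact_max) {
    # all 2^n sign patterns are equally likely under H0
    w_all <- 0
    for (i in seq_len(n))  # distribution by convolution over atoms
      w_all <- as.vector(outer(w_all, c(0, rk[i]), `+`))
    p <- two_sided_from_tails(w_all, rep(1 / length(w_all), length(w_all)), W)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) { p <- 1 } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(W = W, p = p, n_nonzero = n, method = method)
}

#' Per-class score summary with Mann-Whitney comparison
#'
#' Mean and sample standard deviation of the docking scores for actives and
#' decoys separately, the absolute difference of the class means, and the
#' Mann-Whitney U two-sided p-value for the comparison — the per-target
#' summary used when asking whether actives receive systematically stronger
#' predicted affinities than decoys.
#'
#' @param lib a [ranked_library] containing both classes.
#' @return Data frame of class \code{score_class_summary} with one row and
#'   columns \code{mean_active}, \code{sd_active}, \code{mean_decoy},
#'   \code{sd_decoy}, \code{abs_diff}, \code{p_mw}.
#' @export
score_class_summary <- function(lib) {
  check_two_classes(lib)
  sa <- lib$score[lib$label == "active"]
  sd_ <- lib$score[lib$label == "decoy"]
  out <- data.frame(mean_active = mean(sa),
                    sd_active = if (length(sa) > 1L) stats::sd(sa) else 0,
                    mean_decoy = mean(sd_),
                    sd_decoy = if (length(sd_) > 1L) stats::sd(sd_) else 0,
                    abs_diff = abs(mean(sa) - mean(sd_)),
                    p_mw = mann_whitney_u(sa, sd_)$p)
  class(out) <- c("score_class_summary", "data.frame")
  out
}

#' All ranking metrics for one library
#'
#' @param lib a [ranked_library].
#' @param ef_fractions top fractions for the enrichment factors (default 1\%
#'   and 10\%).
#' @param alpha BEDROC exponent.
#' @return One-row data frame of class \code{metric_report}: \code{ef_1pct},
#'   \code{ef_10pct} (named after the default fractions), \code{bedroc20},
#'   \code{auc}, \code{act50}.
#' @export
metric_report <- function(lib, ef_fractions = c(0.01, 0.10), alpha = 20) {
  check_two_classes(lib)
  efs <- vapply(ef_fractions, function(f) enrichment_factor(lib, f), numeric(1))
  out <- data.frame(ef_1pct = efs[1], ef_10pct = efs[2],
                    bedroc20 = bedroc(lib, alpha),
                    auc = enrichment_auc(lib),
                    act50 = act_fraction(lib, 0.5))
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @rdname metric_report
#' @param report a \code{metric_report} (or a data frame of them).
#' @param path output path for a tab-delimited rendering.
#' @export
write_metric_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
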