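# Nonparametric statistics battery for cohorts of characteristic regional
# strains: Mann-Whitney group contrasts, Friedman location comparisons with
# paired-Wilcoxon post hocs, Kruskal-Wallis load-level comparisons,
# Shapiro-Wilk normality screen, and step-down ("linear") Bonferroni / plain
# Bonferroni multiplicity control.

#' Configuration of the statistics battery
#'
#' @param alpha significance level, default 0.05.
#' @param correction multiple-comparison scheme: `"holm"` (the sequentially
#'   rejective, step-down Bonferroni) or `"bonferroni"`.
#' @param exact_threshold largest per-group sample size for which exact
#'   (enumeration) p-values are requested from the rank tests; ties always
#'   fall back to the tie-corrected normal approximation.
#' @return object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05,
                         correction = c("holm", "bonferroni"),
                         exact_threshold = 25L) {
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, correction = correction,
                 exact_threshold = as.integer(exact_threshold)),
            class = "stats_config")
}

.has_ties <- function(x) anyDuplicated(x) > 0L

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test; exact p by enumeration when both groups are at
#' or below `exact_threshold` and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param a,b numeric value vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_threshold see [stats_config()].
#' @return list with `U` (the statistic for group `a`) and `p`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided",
                         exact_threshold = 25L) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  exact <- length(a) <= exact_threshold && length(b) <= exact_threshold &&
    !.has_ties(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Applied to paired differences; zero differences are dropped (the classic
#' treatment). Exact p by sign-pattern enumeration for small n without ties
#' in the absolute differences.
#'
#' @param x,y paired numeric vectors, or `y = NULL` to treat `x` as
#'   differences.
#' @inheritParams mann_whitney
#' @return list with `W` (positive-rank sum) and `p`.
#' @export
wilcoxon_signed <- function(x, y = NULL, alternative = "two.sided",
                            exact_threshold = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  exact <- length(d) <= exact_threshold && !.has_ties(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Friedman test for repeated measures across locations
#'
#' Rank-based comparison of `k` treatments over `n` blocks with tie
#' correction; chi-square reference distribution with `k - 1` df.
#'
#' @param mat numeric matrix, blocks (specimens) in rows, treatments
#'   (locations) in columns; `>= 2` of each.
#' @return list with `chisq` and `p`.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 blocks and 2 treatments", call. = FALSE)
  ht <- stats::friedman.test(mat)
  chisq <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(chisq)) { # complete within-block ties: no evidence at all
    chisq <- 0
    p <- 1
  }
  list(chisq = chisq, p = p)
}

#' Kruskal-Wallis test across independent groups
#'
#' @param groups list of numeric vectors (`>= 2` groups, each non-empty).
#' @return list with `H` (tie-corrected) and `p` (chi-square, `k - 1` df).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 non-empty groups", call. = FALSE)
  ht <- stats::kruskal.test(groups)
  list(H = unname(ht$statistic), p = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector with `3 <= length(x) <= 5000`.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Adjust p-values within a contrast family
#'
#' `"holm"` is the sequentially rejective step-down Bonferroni (often called
#' the linear Bonferroni correction); `"bonferroni"` multiplies by the family
#' size, capped at 1. Adjusted values are monotone in the raw values.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param scheme `"holm"` or `"bonferroni"`.
#' @param alpha significance level for the decisions.
#' @return data.frame with `p`, `p_adj`, `significant`.
#' @export
adjust_pvalues <- function(p, scheme = c("holm", "bonferroni"),
                           alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_adj <- stats::p.adjust(p, method = scheme)
  data.frame(p = p, p_adj = p_adj, significant = !is.na(p_adj) &
               p_adj <= alpha)
}

# ---- study-level battery ---------------------------------------------------

# Region-level characteristic value per specimen/side/load/region/direction:
# body regions average their inner and outer zone rows.
.characteristic <- function(table) {
  agg <- stats::aggregate(strain_pct ~ specimen + group + side + load +
                            region + direction, data = table, FUN = mean)
  names(agg)[names(agg) == "strain_pct"] <- "value"
  agg
}

.zone_characteristic <- function(table) {
  body <- table[table$zone %in% c("inner", "outer"), ]
  body$location <- paste0(body$region, "_", ifelse(body$zone == "inner",
                                                   "in", "out"))
  body
}

#' Run the full nonparametric statistics battery on a cohort table
#'
#' Families of contrasts, mirroring a two-group loading study:
#' \describe{
#'   \item{group}{Mann-Whitney mild vs severe per side, load, region and
#'     direction (uncorrected, reported per contrast).}
#'   \item{location}{Friedman across AH/PI/PH and across the six body zones
#'     within each group, side, direction and load; significant omnibus tests
#'     are followed by pairwise paired Wilcoxon post hocs with the configured
#'     correction applied within each omnibus family.}
#'   \item{attachment}{paired Wilcoxon ARA vs PRA per group, side, direction
#'     and load.}
#'   \item{load}{Kruskal-Wallis across the load levels per group, side,
#'     region and direction, followed by pairwise Mann-Whitney post hocs with
#'     the configured correction.}
#'   \item{normality}{Shapiro-Wilk per direction on the pooled characteristic
#'     values.}
#' }
#'
#' @param table a cohort table as produced by [synthesize_cohort()] or
#'   [run_study()].
#' @param config a [stats_config()].
#' @return data.frame (`stats_report`): one row per contrast with `family`,
#'   `contrast`, `test`, `statistic`, `p`, `p_adj`, `significant`, `note`.
#' @export
run_study_stats <- function(table, config = stats_config()) {
  stopifnot(inherits(config, "stats_config"))
  ch <- .characteristic(table)
  rows <- list()
  push <- function(family, contrast, test, statistic, p,
                   p_adj = NA_real_, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, contrast = contrast, test = test,
      statistic = statistic, p = p, p_adj = p_adj,
      significant = NA, note = note, stringsAsFactors = FALSE)
  }
  groups <- unique(ch$group)
  two_groups <- all(c("mild", "severe") %in% groups)
  loads <- sort(unique(ch$load))
  et <- config$exact_threshold

  # -- group contrasts (Mann-Whitney mild vs severe) --
  if (two_groups) {
    cells <- unique(ch[, c("side", "load", "region", "direction")])
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      sub <- ch[ch$side == cl$side & ch$load == cl$load &
                  ch$region == cl$region & ch$direction == cl$direction, ]
      a <- sub$value[sub$group == "mild"]
      b <- sub$value[sub$group == "severe"]
      if (!length(a) || !length(b)) {
        push("group", .ct(cl), "mann_whitney", NA_real_, NA_real_,
             note = "missing cell")
        next
      }
      mw <- mann_whitney(a, b, exact_threshold = et)
      push("group", .ct(cl), "mann_whitney", mw$U, mw$p)
    }
  }

  # -- location contrasts: Friedman + post hoc paired Wilcoxon --
  zch <- .zone_characteristic(table)
  for (g in groups) for (sd_ in unique(ch$side))
    for (dir in unique(ch$direction)) for (ld in loads) {
      for (fam in c("regions", "zones")) {
        if (fam == "regions") {
          sub <- ch[ch$group == g & ch$side == sd_ & ch$direction == dir &
                      ch$load == ld & ch$region %in% c("AH", "PI", "PH"), ]
          wide <- .wide(sub, "region", c("AH", "PI", "PH"))
        } else {
          sub <- zch[zch$group == g & zch$side == sd_ &
                       zch$direction == dir & zch$load == ld, ]
          sub$value <- sub$strain_pct
          wide <- .wide(sub, "location",
                        c("AH_in", "AH_out", "PI_in", "PI_out",
                          "PH_in", "PH_out"))
        }
        lab <- sprintf("%s|%s|%s|BW%d|%s", g, sd_, dir, round(100 * ld), fam)
        if (is.null(wide) || nrow(wide) < 2L) {
          push("location", lab, "friedman", NA_real_, NA_real_,
               note = "missing cell")
          next
        }
        fr <- friedman(wide)
        push("location", lab, "friedman", fr$chisq, fr$p)
        if (!is.na(fr$p) && fr$p <= config$alpha) {
          prs <- utils::combn(colnames(wide), 2L)
          ps <- apply(prs, 2L, function(pp)
            wilcoxon_signed(wide[, pp[1]], wide[, pp[2]],
                            exact_threshold = et)$p)
          adj <- adjust_pvalues(ps, config$correction, config$alpha)
          for (j in seq_along(ps))
            push("location_posthoc",
                 paste0(lab, ":", prs[1, j], " vs ", prs[2, j]),
                 "wilcoxon_signed", NA_real_, adj$p[j], adj$p_adj[j])
        }
      }
    }

  # -- attachment contrast: paired Wilcoxon ARA vs PRA --
  for (g in groups) for (sd_ in unique(ch$side))
    for (dir in unique(ch$direction)) for (ld in loads) {
      sub <- ch[ch$group == g & ch$side == sd_ & ch$direction == dir &
                  ch$load == ld & ch$region %in% c("ARA", "PRA"), ]
      wide <- .wide(sub, "region", c("ARA", "PRA"))
      lab <- sprintf("%s|%s|%s|BW%d|ARA vs PRA", g, sd_, dir,
                     round(100 * ld))
      if (is.null(wide) || nrow(wide) < 2L) {
        push("attachment", lab, "wilcoxon_signed", NA_real_, NA_real_,
             note = "missing cell")
        next
      }
      ws <- tryCatch(wilcoxon_signed(wide[, "ARA"], wide[, "PRA"],
                                     exact_threshold = et),
                     error = function(e) NULL)
      if (is.null(ws)) push("attachment", lab, "wilcoxon_signed", NA_real_,
                            NA_real_, note = "all differences zero")
      else push("attachment", lab, "wilcoxon_signed", ws$W, ws$p)
    }

  # -- load-level contrasts: Kruskal-Wallis + pairwise post hocs --
  if (length(loads) >= 2L) {
    cells <- unique(ch[, c("group", "side", "region", "direction")])
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      sub <- ch[ch$group == cl$group & ch$side == cl$side &
                  ch$region == cl$region & ch$direction == cl$direction, ]
      gl <- lapply(loads, function(ld) sub$value[sub$load == ld])
      lab <- sprintf("%s|%s|%s|%s|loads", cl$group, cl$side, cl$region,
                     cl$direction)
      if (any(!lengths(gl))) {
        push("load", lab, "kruskal_wallis", NA_real_, NA_real_,
             note = "missing cell")
        next
      }
      kw <- kruskal_wallis(gl)
      push("load", lab, "kruskal_wallis", kw$H, kw$p)
      if (!is.na(kw$p) && kw$p <= config$alpha) {
        prs <- utils::combn(seq_along(loads), 2L)
        ps <- apply(prs, 2L, function(pp)
          mann_whitney(gl[[pp[1]]], gl[[pp[2]]], exact_threshold = et)$p)
        adj <- adjust_pvalues(ps, config$correction, config$alpha)
        for (j in seq_along(ps))
          push("load_posthoc",
               sprintf("%s:BW%d vs BW%d", lab, round(100 * loads[prs[1, j]]),
                       round(100 * loads[prs[2, j]])),
               "mann_whitney", NA_real_, adj$p[j], adj$p_adj[j])
      }
    }
  }

  # -- normality screen --
  for (dir in unique(ch$direction)) {
    v <- ch$value[ch$direction == dir]
    if (length(v) >= 3L && length(v) <= 5000L) {
      sw <- tryCatch(shapiro_wilk(v), error = function(e) NULL)
      if (is.null(sw))
        push("normality", dir, "shapiro_wilk", NA_real_, NA_real_,
             note = "degenerate sample")
      else
        push("normality", dir, "shapiro_wilk", sw$W, sw$p)
    }
  }

  rep <- do.call(rbind, rows)
  rep$significant <- ifelse(is.na(rep$p_adj),
                            !is.na(rep$p) & rep$p <= config$alpha,
                            rep$p_adj <= config$alpha)
  class(rep) <- c("stats_report", "data.frame")
  attr(rep, "alpha") <- config$alpha
  attr(rep, "correction") <- config$correction
  rep
}

.ct <- function(cl) sprintf("%s|BW%d|%s|%s", cl$side, round(100 * cl$load),
                            cl$region, cl$direction)

# specimen x level wide matrix of characteristic values; NULL when incomplete
.wide <- function(sub, col, levels) {
  if (!nrow(sub)) return(NULL)
  sp <- sort(unique(sub$specimen))
  w <- matrix(NA_real_, length(sp), length(levels),
              dimnames = list(sp, levels))
  for (lv in levels) {
    s2 <- sub[sub[[col]] == lv, ]
    w[match(s2$specimen, sp), lv] <- s2$value
  }
  w <- w[stats::complete.cases(w), , drop = FALSE]
  if (!nrow(w)) NULL else w
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> ", nrow(x), " contrasts; ",
      sum(x$significant, na.rm = TRUE), " significant at alpha = ",
      attr(x, "alpha"), " (", attr(x, "correction"), " correction)\n",
      sep = "")
  fams <- table(x$family)
  for (f in names(fams)) cat("  ", f, ": ", fams[[f]], "\n", sep = "")
  invisible(x)
}
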