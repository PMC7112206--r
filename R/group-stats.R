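#' Assemble group samples for comparison
#'
#' @param values numeric outcome values (viability %, percent positive, or
#'   AU).
#' @param group group label per value (factor or character).
#' @return data.frame of class `group_samples` with columns `value`,
#'   `group` (factor, levels in first-appearance order).
#' @export
group_samples <- function(values, group) {
  if (length(values) != length(group)) stop("values and group lengths differ")
  g <- factor(group, levels = unique(as.character(group)))
  df <- data.frame(value = as.numeric(values), group = g)
  counts <- table(df$group)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) stop("every group needs at least 2 values")
  structure(df, class = c("group_samples", "data.frame"))
}

#' Kruskal--Wallis rank-based omnibus test
#'
#' ANOVA on ranks: the tie-corrected Kruskal--Wallis H statistic with a
#' chi-square p-value on `k - 1` degrees of freedom. When all pooled values
#' are identical, the tie-correction limit gives `H = 0`, `p = 1`.
#'
#' @param data a [group_samples()] data.frame.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(data) {
  if (length(unique(data$value)) == 1L)
    return(list(H = 0, df = nlevels(data$group) - 1L, p = 1))
  kt <- kruskal.test(value ~ group, data = data)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise post-hoc comparisons
#'
#' `tukey`: Tukey's honestly-significant-difference test on the group means
#' (studentized range). `dunn`: Dunn's rank-based z test with tie
#' correction, the standard companion of a Kruskal--Wallis omnibus;
#' p-values are two-sided and unadjusted.
#'
#' @param data a [group_samples()] data.frame.
#' @param method `"tukey"` or `"dunn"`.
#' @return symmetric matrix of pairwise p-values with unit diagonal,
#'   dimnames = group levels, attribute `method`.
#' @export
pairwise_posthoc <- function(data, method = c("tukey", "dunn")) {
  method <- match.arg(method)
  lev <- levels(data$group)
  k <- length(lev)
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  if (method == "tukey") {
    fit <- aov(value ~ group, data = data)
    tk <- TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      p[a, b] <- p[b, a] <- tk[i, "p adj"]
    }
  } else {
    N <- nrow(data)
    rk <- rank(data$value)
    rbar <- tapply(rk, data$group, mean)
    n <- as.numeric(table(data$group))
    ties <- table(data$value)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    base_var <- N * (N + 1) / 12 - tie_term
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
      zval <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      p[i, j] <- p[j, i] <- 2 * pnorm(-abs(zval))
    }
  }
  attr(p, "method") <- method
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb assignment: start from one letter covering all groups;
#' for every significant pair split each letter containing both groups into
#' two copies, one without each member; absorb letters that are subsets of
#' others. Two groups share at least one letter iff their pairwise p-value
#' is `>= alpha`. Deterministic given the matrix's group order.
#'
#' @param p symmetric pairwise p-value matrix with group dimnames.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(p, alpha = 0.05) {
  if (!isTRUE(all.equal(p, t(p)))) stop("p matrix must be symmetric")
  k <- nrow(p)
  groups <- rownames(p)
  if (is.null(groups)) groups <- as.character(seq_len(k))
  sets <- list(seq_len(k))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (p[i, j] >= alpha) next
      new_sets <- list()
      changed <- FALSE
      for (s in sets) {
        if (i %in% s && j %in% s) {
          changed <- TRUE
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      if (changed) {
        # absorb: drop sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
            keep[a] <- FALSE
        }
        sets <- new_sets[keep]
      }
    }
  }
  sets <- sets[lengths(sets) > 0]
  letters_out <- setNames(rep("", k), groups)
  for (s_idx in seq_along(sets)) {
    l <- letters[(s_idx - 1) %% 26 + 1]
    if (s_idx > 26) l <- paste0(l, (s_idx - 1) %/% 26)
    for (g in sets[[s_idx]])
      letters_out[g] <- paste0(letters_out[g], l)
  }
  letters_out
}

#' Choose the post-hoc method from per-group normality
#'
#' Shapiro--Wilk on every group at `alpha`; Tukey's test when all groups
#' pass, Dunn's test otherwise. Groups with fewer than 3 values cannot be
#' tested for normality: Dunn's test is chosen with a warning.
#'
#' @param data a [group_samples()] data.frame.
#' @param alpha normality test level (default 0.05).
#' @return `"tukey"` or `"dunn"`, with attribute `normal_per_group`.
#' @export
choose_method <- function(data, alpha = 0.05) {
  lev <- levels(data$group)
  normal <- setNames(rep(NA, length(lev)), lev)
  for (g in lev) {
    v <- data$value[data$group == g]
    if (length(v) < 3L) {
      warning("group '", g, "' has fewer than 3 values; ",
              "normality untestable, using Dunn's test")
      return(structure("dunn", normal_per_group = normal))
    }
    normal[g] <- if (length(unique(v)) == 1L) FALSE
                 else shapiro.test(v)$p.value >= alpha
  }
  structure(if (all(normal)) "tukey" else "dunn",
            normal_per_group = normal)
}

#' Full between-group comparison report
#'
#' Kruskal--Wallis omnibus, normality-driven post-hoc choice (overridable),
#' pairwise p-values and a compact letter display at `alpha`.
#'
#' @param data a [group_samples()] data.frame.
#' @param alpha significance level (default 0.05).
#' @param method post-hoc method; `"auto"` (default) picks via
#'   [choose_method()].
#' @return list of class `comparison_report`: `summary` (per-group n, mean,
#'   sd, median), `omnibus`, `method`, `normal_per_group`, `pairwise_p`,
#'   `letters`, `alpha`.
#' @export
compare_groups <- function(data, alpha = 0.05,
                           method = c("auto", "tukey", "dunn")) {
  method <- match.arg(method)
  omnibus <- kruskal_wallis(data)
  normal <- NULL
  if (method == "auto") {
    m <- choose_method(data, alpha)
    normal <- attr(m, "normal_per_group")
    method <- as.character(m)
  }
  pw <- pairwise_posthoc(data, method)
  lets <- compact_letters(pw, alpha)
  summ <- do.call(rbind, lapply(levels(data$group), function(g) {
    v <- data$value[data$group == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v),
               median = median(v))
  }))
  summ$letters <- lets[summ$group]
  structure(list(summary = summ, omnibus = omnibus, method = method,
                 normal_per_group = normal, pairwise_p = pw,
                 letters = lets, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> Kruskal-Wallis H = %.3f (df = %d), p = %.4g\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p))
  cat(sprintf("  post-hoc: %s (alpha = %g); groups sharing a letter are not\n",
              x$method, x$alpha))
  cat("  significantly different pairwise\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
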