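test_that("Kruskal-Wallis H matches the rank-formula oracle, with and without ties", {
  g <- group_samples(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  res <- kruskal_wallis(g)
  expect_equal(res$H, oracle_kw_h(g$value, g$group))
  expect_equal(res$df, 1L)

  set.seed(83)
  v <- round(rnorm(30, 10, 2))  # rounding forces ties
  grp <- rep(c("a", "b", "c"), each = 10)
  g2 <- group_samples(v, grp)
  expect_equal(kruskal_wallis(g2)$H, oracle_kw_h(v, grp))
})

test_that("identical groups give H = 0 and p = 1", {
  g <- group_samples(rep(5, 8), rep(c("a", "b"), each = 4))
  res <- kruskal_wallis(g)
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
})

test_that("H is invariant under strictly monotone transforms of the data", {
  set.seed(89)
  v <- rnorm(24)
  grp <- rep(c("a", "b", "c"), each = 8)
  h0 <- kruskal_wallis(group_samples(v, grp))$H
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) atan(x) * 10)) {
    expect_equal(kruskal_wallis(group_samples(f(v), grp))$H, h0)
  }
})

test_that("post-hoc p-values: separated groups significant, identical groups not", {
  set.seed(97)
  a <- rnorm(8, 0, 0.2)
  b <- rnorm(8, 10, 0.2)
  g <- group_samples(c(a, b), rep(c("a", "b"), each = 8))
  for (m in c("tukey", "dunn")) {
    p <- pairwise_posthoc(g, m)
    expect_lt(p["a", "b"], 0.001)
    expect_equal(unname(diag(p)), c(1, 1))
    expect_equal(p["a", "b"], p["b", "a"])
  }
  # permutation oracle: the observed mean difference is never exceeded
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  exceed <- 0L
  set.seed(98)
  for (i in 1:10000) {
    idx <- sample(16, 8)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs)
      exceed <- exceed + 1L
  }
  expect_lt((exceed + 1) / 10001, 0.001)

  same <- group_samples(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_gt(pairwise_posthoc(same, "dunn")["a", "b"], 0.99)
})

test_that("Dunn p-values are monotone-transform invariant; Tukey p-values are not", {
  set.seed(101)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  grp <- rep(c("a", "b", "c"), each = 8)
  g1 <- group_samples(v, grp)
  g2 <- group_samples(exp(v), grp)
  expect_equal(pairwise_posthoc(g1, "dunn"), pairwise_posthoc(g2, "dunn"))
  tk1 <- pairwise_posthoc(g1, "tukey")
  tk2 <- pairwise_posthoc(g2, "tukey")
  expect_false(isTRUE(all.equal(tk1, tk2)))
})

test_that("compact letters: the two degenerate structures", {
  lev <- c("g1", "g2", "g3", "g4")
  p_ns <- matrix(1, 4, 4, dimnames = list(lev, lev))
  expect_true(all(compact_letters(p_ns) == "a"))
  p_sig <- matrix(0, 4, 4, dimnames = list(lev, lev))
  diag(p_sig) <- 1
  lets <- compact_letters(p_sig)
  expect_equal(length(unique(lets)), 4L)
})

test_that("compact letters: sharing structure equals the pairwise significance relation", {
  # random symmetric p matrices over 5 groups; two groups must share a
  # letter iff their p >= alpha
  set.seed(103)
  lev <- paste0("g", 1:5)
  for (rep in 1:20) {
    p <- matrix(1, 5, 5, dimnames = list(lev, lev))
    for (i in 1:4) for (j in (i + 1):5)
      p[i, j] <- p[j, i] <- sample(c(0.001, 0.2, 0.8), 1)
    lets <- compact_letters(p, alpha = 0.05)
    for (i in 1:4) for (j in (i + 1):5) {
      share <- length(intersect(strsplit(lets[i], "")[[1]],
                                strsplit(lets[j], "")[[1]])) > 0
      expect_equal(share, p[i, j] >= 0.05,
                   info = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
})

test_that("compact letters are order-independent up to renaming", {
  lev <- paste0("g", 1:5)
  set.seed(107)
  p <- matrix(1, 5, 5, dimnames = list(lev, lev))
  for (i in 1:4) for (j in (i + 1):5)
    p[i, j] <- p[j, i] <- sample(c(0.01, 0.5), 1)
  lets <- compact_letters(p)
  perm <- c(3, 1, 5, 2, 4)
  lets_p <- compact_letters(p[perm, perm])
  share <- function(l, a, b)
    length(intersect(strsplit(l[a], "")[[1]], strsplit(l[b], "")[[1]])) > 0
  for (a in lev) for (b in setdiff(lev, a))
    expect_equal(share(lets, a, b), share(lets_p, a, b))
})

test_that("normality drives the post-hoc choice", {
  set.seed(109)
  gauss <- group_samples(rnorm(150), rep(paste0("g", 1:3), each = 50))
  expect_equal(as.character(choose_method(gauss)), "tukey")
  heavy <- group_samples(rcauchy(90), rep(paste0("g", 1:3), each = 30))
  expect_equal(as.character(choose_method(heavy)), "dunn")
  tiny <- group_samples(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_warning(m <- choose_method(tiny), "fewer than 3")
  expect_equal(as.character(m), "dunn")
})

test_that("omnibus type-I error is calibrated at the nominal 5% level", {
  set.seed(113)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    v <- rnorm(40)
    grp <- rep(paste0("g", 1:5), each = 8)
    if (kruskal_wallis(group_samples(v, grp))$p < 0.05)
      rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("a 2-SD shifted group is detected with high power", {
  set.seed(127)
  n_sim <- 500
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    v <- c(rnorm(8, 2), rnorm(32))
    grp <- rep(paste0("g", 1:5), each = 8)
    if (kruskal_wallis(group_samples(v, grp))$p < 0.05)
      rejections <- rejections + 1L
  }
  expect_gt(rejections / n_sim, 0.8)
})

test_that("compare_groups assembles a coherent report", {
  set.seed(131)
  v <- c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 5))
  grp <- rep(c("ctrl", "sham", "injured"), each = 8)
  rep_ <- compare_groups(group_samples(v, grp))
  expect_s3_class(rep_, "comparison_report")
  expect_lt(rep_$omnibus$p, 0.01)
  expect_true(rep_$method %in% c("tukey", "dunn"))
  expect_equal(rownames(rep_$pairwise_p), c("ctrl", "sham", "injured"))
  # letter display consistent with pairwise significances
  for (i in 1:2) for (j in (i + 1):3) {
    share <- length(intersect(strsplit(rep_$letters[i], "")[[1]],
                              strsplit(rep_$letters[j], "")[[1]])) > 0
    expect_equal(share, rep_$pairwise_p[i, j] >= 0.05)
  }
})
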