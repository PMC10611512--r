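make_feature_dataset <- function(n_subj = 6, shift = 0, seed = 1,
                                 n_chan = 4, noise = 0.05) {
  set.seed(seed)
  bands <- eeg_bands()$name
  feat_names <- paste(rep(standard_channel_names()[seq_len(n_chan)],
                          each = 5), bands, sep = ".")
  emotions <- c("calmness", "happiness", "fear", "sadness")
  labs <- expand.grid(order = 1:5, trial = 1:2, emotion = emotions,
                      subject = seq_len(n_subj),
                      stringsAsFactors = FALSE)[, c("subject", "emotion",
                                                    "trial", "order")]
  base <- 2
  X <- matrix(base + rnorm(nrow(labs) * length(feat_names), 0, noise),
              nrow(labs), length(feat_names),
              dimnames = list(NULL, feat_names))
  # optional planted positive-group elevation
  pos <- labs$emotion %in% c("calmness", "happiness")
  X[pos, ] <- X[pos, ] + shift
  design <- session_design(2)
  emorec_dataset(X, labs, design, "eeg")
}

test_that("grouping by dimension produces per-subject group means", {
  d <- make_feature_dataset()
  g <- group_by_dimension(d, dimension = "valence")
  expect_equal(dim(g$positive), c(6, 20))
  expect_equal(dim(g$negative), c(6, 20))

  # a subject whose groups see identical data gives identical rows
  d0 <- make_feature_dataset(shift = 0, noise = 0)
  g0 <- group_by_dimension(d0, dimension = "valence")
  expect_equal(g0$positive, g0$negative, tolerance = 1e-12)

  # all scores on one side -> every subject loses a group
  sc <- c(calmness = 5, happiness = 5, fear = 4, sadness = 4)
  expect_error(suppressWarnings(group_by_dimension(d, scores = sc)),
               "empty group")
})

test_that("volcano statistics recover planted effects and null identities", {
  g <- group_by_dimension(make_feature_dataset(shift = 0.4, noise = 0.05),
                          dimension = "valence")
  v <- volcano_stats(g)
  expect_true(all(v$regulation == "up"))
  expect_true(all(v$significant))
  expect_true(all(v$f > 201 / 200))

  # identical groups: F = 1, nothing significant
  g0 <- group_by_dimension(make_feature_dataset(noise = 0),
                           dimension = "valence")
  v0 <- volcano_stats(g0)
  expect_equal(v0$f, rep(1, nrow(v0)))
  expect_equal(v0$log2_f, rep(0, nrow(v0)))
  expect_true(all(v0$regulation == "none"))

  # vectorized paired t matches stats::t.test
  g1 <- group_by_dimension(make_feature_dataset(shift = 0.05, seed = 4),
                           dimension = "valence")
  v1 <- volcano_stats(g1)
  j <- 7
  ref <- t.test(g1$positive[, j], g1$negative[, j], paired = TRUE)
  expect_equal(v1$p[j], ref$p.value, tolerance = 1e-12)

  # swapping groups inverts F and keeps p
  gs <- g1
  tmp <- gs$positive; gs$positive <- gs$negative; gs$negative <- tmp
  vs <- volcano_stats(gs)
  expect_equal(vs$log2_f, -v1$log2_f, tolerance = 1e-12)
  expect_equal(vs$p, v1$p, tolerance = 1e-12)

  # every regulated point satisfies both thresholds
  expect_true(all(v1$f[v1$regulation == "up"] > 201 / 200))
  expect_true(all(v1$p[v1$regulation != "none"] < 0.05))

  # the rank-based alternative runs and agrees on the null
  vk <- volcano_stats(g0, test = "kruskal")
  expect_true(all(vk$regulation == "none"))
})

test_that("type-I error of the volcano pipeline is calibrated", {
  set.seed(77)
  n_rep <- 40
  hits <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    P <- matrix(rnorm(15 * 50), 15, 50)
    N <- matrix(rnorm(15 * 50), 15, 50)
    g <- structure(list(positive = 3 + P, negative = 3 + N,
                        dimension = "valence", subjects = 1:15,
                        feature_names = paste0("FP1.b", 1:50)),
                   class = "emorec_groups")
    v <- volcano_stats(g)
    hits <- hits + sum(v$p < 0.05)
    total <- total + nrow(v)
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("topography mapping is a faithful bookkeeping of calls", {
  g <- group_by_dimension(make_feature_dataset(shift = 0.4),
                           dimension = "valence")
  v <- volcano_stats(g)
  topo <- map_topography(v)
  expect_equal(nrow(topo), nrow(v))
  expect_equal(table(topo$regulation), table(v$regulation))
  expect_true(all(c("x", "y") %in% names(topo)))

  bad <- v
  bad$channel[1] <- "XX9"
  expect_error(map_topography(bad), "unknown channel")

  v0 <- volcano_stats(group_by_dimension(make_feature_dataset(noise = 0),
                                         dimension = "valence"))
  expect_true(all(map_topography(v0)$regulation == "none"))
})

test_that("shrinkage verdicts require joint monotone decline", {
  g_big <- group_by_dimension(make_feature_dataset(shift = 0.4, seed = 1),
                              dimension = "valence")
  g_mid <- group_by_dimension(make_feature_dataset(shift = 0.1, seed = 2),
                              dimension = "valence")
  g_null <- group_by_dimension(make_feature_dataset(shift = 0, seed = 3),
                               dimension = "valence")
  v <- lapply(list(g_big, g_mid, g_null), volcano_stats)
  sh <- cross_session_shrinkage(v)
  expect_true(all(sh$shrinkage))
  expect_true(all(sh$n_sig_s1 >= sh$n_sig_s3))

  # identical distributions: no verdicts
  v_same <- lapply(1:3, function(i) volcano_stats(g_null))
  sh0 <- cross_session_shrinkage(v_same)
  expect_false(any(sh0$shrinkage))
})
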