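test_that("reading and validating dated trees handles the basic cases", {
  tr <- as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(tr$crown_age, 2)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(branching_times(tr), c(2, 1))

  f <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  expect_equal(crown_age(read_tree(f)), 2)

  # polytomies are rejected, not resolved
  expect_error(as_dated_tree(ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")),
               "polytomies")
  # negative branch lengths are an error
  expect_error(as_dated_tree(ape::read.tree(text = "((A:1,B:-1):1,C:2);")),
               "negative")
  # missing branch lengths are an error
  expect_error(as_dated_tree(ape::read.tree(text = "((A,B),C);")),
               "branch lengths")
})

test_that("tips just below the ultrametricity tolerance snap to the present", {
  # crown age 50; one tip ends 2e-5 My early (recently extinct): within
  # 1e-6 * 50 tolerance, snapped to 0
  txt <- sprintf("((A:%0.6f,B:25):25,C:50);", 25 - 2e-5)
  tr <- as_dated_tree(ape::read.tree(text = txt))
  expect_equal(max(abs(tr$node_age[1:3])), 0)
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  # a deviation beyond tolerance is an error, not a silent repair
  txt_bad <- "((A:24.9,B:25):25,C:50);"
  expect_error(as_dated_tree(ape::read.tree(text = txt_bad)), "ultrametric")
})

test_that("branching times and LTT agree with hand readings", {
  tr4 <- as_dated_tree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
  expect_equal(branching_times(tr4), c(3, 2, 1))
  lt <- ltt_curve(tr4)
  expect_equal(lt$lineages, c(2L, 3L, 4L, 4L))
  expect_equal(lt$age, c(3, 2, 1, 0))
  # n - 1 branching times for any n-tip binary tree
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 37, seed = 1)
  expect_length(branching_times(tr), 36L)
  expect_equal(ltt_curve(tr)$lineages[1L], 2L)
  expect_equal(tail(ltt_curve(tr)$lineages, 1L), 37L)
})

test_that("patristic distances match a brute-force path oracle", {
  tr <- as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  D <- patristic_matrix(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(diag(D), setNames(rep(0, 3), c("A", "B", "C")))
  for (s in 1:3) {
    tr <- simulate_bd_tree(0.3, 0.1, stop = "taxa", n = 20, seed = s)
    D <- patristic_matrix(tr)
    expect_equal(D, oracle_patristic(tr), tolerance = 1e-12)
    # ultrametric identity: d(i,j) = 2 * MRCA age (tip MRCA ages are 0)
    mm <- ape::mrca(tr)
    ages <- matrix(tr$node_age[mm], nrow(mm))
    expect_equal(unname(D), 2 * ages, tolerance = 1e-10)
  }
})

test_that("gamma statistic is centred for Yule trees and negative for root-heavy trees", {
  g <- vapply(1:400, function(s)
    gamma_statistic(simulate_bd_tree(1, 0, stop = "taxa", n = 50, seed = s)), 0)
  expect_lt(abs(mean(g)), 3 / sqrt(length(g)))   # mean 0 within 3 Monte-Carlo s.e.
  expect_lt(abs(var(g) - 1), 0.2)                # variance near 1
  # comb tree with internodes pushed toward the root: strongly negative
  comb <- as_dated_tree(ape::read.tree(
    text = "(((A:0.1,B:0.1):0.05,C:0.15):0.05,D:0.2);"))
  expect_lt(gamma_statistic(comb), 0)
  expect_error(gamma_statistic(as_dated_tree(ape::read.tree(text = "(A:1,B:1);"))),
               "3 tips")
})

test_that("clade extraction returns the crown subtree of the named tips", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 30, seed = 5)
  expect_equal(extract_clade(tr, tr$tip.label)$crown_age, tr$crown_age)
  # two sister tips give a cherry whose crown age is their divergence time
  e <- which(tr$edge[, 2L] <= 30)
  sis <- NULL
  for (nd in unique(tr$edge[, 1L])) {
    kids <- tr$edge[tr$edge[, 1L] == nd, 2L]
    if (all(kids <= 30)) { sis <- kids; anc <- nd; break }
  }
  cl <- extract_clade(tr, tr$tip.label[sis])
  expect_equal(ape::Ntip(cl), 2L)
  expect_equal(cl$crown_age, tr$node_age[anc])
  expect_error(extract_clade(tr, c("nope")), "unknown tip")
})

test_that("richness tables validate and give clade sampling fractions", {
  tr <- simulate_bd_tree(0.2, 0, stop = "taxa", n = 10, seed = 2)
  rich <- data.frame(tip_label = tr$tip.label[1:2], n_species = c(3L, 2L))
  expect_equal(sampling_fraction(tr, rich), 10 / 13)
  expect_equal(sampling_fraction(tr, NULL), 1)
  expect_error(sampling_fraction(tr, data.frame(tip_label = "t1", n_species = 0L)),
               "positive")
  f <- tempfile(fileext = ".csv")
  write.csv(rich, f, row.names = FALSE)
  expect_equal(read_richness(f)$n_species, c(3L, 2L))
})
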