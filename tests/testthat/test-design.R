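# Sequence designer: Pareto filtering, brute-force oracle, GA behavior.

make_cand <- function(pre, post, obj) {
  structure(list(pre_aptamer = pre, post_aptamer = post,
                 prediction = list(tir_bound = 1, tir_unbound = 1),
                 objectives = c(r_max = obj[1], tir_on = obj[2],
                                neg_tir_off = obj[3])),
            class = "design_candidate")
}

tiny_spec <- function(...) {
  design_spec(fix_hairpin_apt(), fix_cds, mode = "OFF",
              length_range = c(2L, 2L), post_scaffold = fix_sd_cassette,
              pop_size = 8L, generations = 4L, seed = 42L, ...)
}

test_that("pareto_filter matches an O(n^2) dominance oracle on random triples", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    obj <- matrix(stats::runif(3 * n), ncol = 3)
    cands <- lapply(seq_len(n), function(k)
      make_cand(sprintf("P%02d", k), sprintf("Q%02d", k), obj[k, ]))
    got <- pareto_filter(cands)
    # independent double-loop dominance check
    nondom <- vapply(seq_len(n), function(i) {
      !any(vapply(seq_len(n), function(j) {
        i != j && all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ])
      }, TRUE))
    }, TRUE)
    expect_setequal(vapply(got, `[[`, "", "pre_aptamer"),
                    sprintf("P%02d", which(nondom)))
    # stable order: descending r_max
    r <- vapply(got, function(x) x$objectives[["r_max"]], 0)
    expect_true(all(diff(r) <= 0))
  }
})

test_that("pareto_filter edge cases", {
  a <- make_cand("A", "", c(1, 1, 1))
  b <- make_cand("C", "", c(2, 2, 2))
  d <- make_cand("G", "", c(2, 2, 2))
  expect_error(pareto_filter(list()), ">= 1")
  expect_length(pareto_filter(list(a)), 1L)
  # dominated candidate absent
  expect_equal(vapply(pareto_filter(list(a, b)), `[[`, "", "pre_aptamer"), "C")
  # all-equal objectives: all retained
  expect_length(pareto_filter(list(b, d)), 2L)
})

test_that("search-space arithmetic spans 4^L sequences", {
  expect_equal(log10_design_space(44), 26)
  expect_equal(log10_design_space(55), 33)
  expect_equal(log10_design_space(0), 0)
})

test_that("design_spec rejects infeasible length ranges", {
  apt <- fix_hairpin_apt()
  short_apt <- aptamer_spec("mini", "GCGCA", ".....", 1e-8)
  expect_error(design_spec(short_apt, fix_cds, length_range = c(0L, 1L)),
               "host an SD")
  expect_error(design_spec(apt, fix_cds, pop_size = 2L))
})

test_that("brute force refuses oversized spaces with an estimate", {
  spec <- design_spec(fix_hairpin_apt(), fix_cds, length_range = c(44L, 55L))
  expect_error(brute_force_design(spec), "brute-force limit")
})

test_that("brute force enumerates the tiny space deterministically", {
  spec <- tiny_spec()
  bf1 <- brute_force_design(spec)
  bf2 <- brute_force_design(spec)
  # 3 splits x 4^2 = 48 candidates, none lost to the AUG filter here
  expect_equal(bf1$n_enumerated, 48L)
  expect_identical(bf1$best$pre_aptamer, bf2$best$pre_aptamer)
  expect_identical(bf1$best$post_aptamer, bf2$best$post_aptamer)
  expect_identical(bf1$best$objectives, bf2$best$objectives)
  # global optimum: nothing in the table beats it on r_max
  rs <- vapply(bf1$candidates, function(x) x$objectives[["r_max"]], 0)
  expect_equal(bf1$best$objectives[["r_max"]], max(rs))
})

test_that("the GA is seed-reproducible, constraint-respecting and elitist", {
  spec <- tiny_spec()
  ga1 <- design_switches(spec)
  ga2 <- design_switches(spec)
  expect_identical(as.data.frame(ga1), as.data.frame(ga2))
  expect_identical(attr(ga1, "seed"), 42L)
  # lengths within range, aptamer untouched, motif-free
  for (cand in ga1) {
    L <- nchar(cand$pre_aptamer) + nchar(cand$post_aptamer)
    expect_true(L >= 2L && L <= 2L)
    expect_false(grepl("AUG", cand$pre_aptamer, fixed = TRUE))
    expect_false(grepl("AUG", cand$post_aptamer, fixed = TRUE))
  }
  # best r_max is non-decreasing across generations (elitism)
  trace <- attr(ga1, "best_r_max_trace")
  expect_true(all(diff(trace) >= -1e-12))
  # bounded by the brute-force optimum
  bf <- brute_force_design(spec)
  expect_lte(ga1[[1]]$objectives[["r_max"]],
             bf$best$objectives[["r_max"]] + 1e-12)
})

test_that("designed candidates respect a variable length range", {
  apt <- fix_hairpin_apt()
  spec <- design_spec(apt, fix_cds, mode = "OFF", length_range = c(2L, 4L),
                      post_scaffold = fix_sd_cassette, pop_size = 6L,
                      generations = 3L, seed = 9L)
  ga <- design_switches(spec)
  for (cand in ga) {
    L <- nchar(cand$pre_aptamer) + nchar(cand$post_aptamer)
    expect_true(L >= 2L && L <= 4L)
  }
})
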