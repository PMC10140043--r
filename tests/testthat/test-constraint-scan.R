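# Alternate-constraint analysis: enumeration, rebuild conservation,
# grid identity and constraint selection.

test_that("subconstraint enumeration is complete and refolds substrings", {
  apt4 <- aptamer_spec("tiny", "GCAU", "....", 1e-8)
  subs <- enumerate_subconstraints(apt4)
  expect_length(subs, 10L)  # L(L+1)/2
  ij <- t(vapply(subs, function(s) c(s$i, s$j), integer(2)))
  expect_false(any(duplicated(ij)))
  # single-nucleotide subconstraints are unconstrained dots
  singles <- Filter(function(s) s$i == s$j, subs)
  expect_true(all(vapply(singles, `[[`, "", "substructure") == "."))

  apt <- fix_hairpin_apt()
  L <- nchar(apt$sequence)
  subs <- enumerate_subconstraints(apt)
  expect_length(subs, L * (L + 1L) / 2L)
  # full-length cell: refold equals the declared (MFE-true) structure
  full <- Filter(function(s) s$i == 1L && s$j == L, subs)[[1]]
  expect_equal(full$substructure, apt$bound_structure)
  # every substructure has matching length
  for (s in subs) expect_equal(nchar(s$substructure), s$j - s$i + 1L)
})

test_that("rebuilding conserves the assembled mRNA for every subconstraint", {
  x <- fix_construct(3)
  m0 <- assemble_mrna(x)
  subs <- enumerate_subconstraints(x$aptamer)
  for (s in subs[seq(1, length(subs), by = 7)]) {
    y <- rebuild_construct(x, s)
    m1 <- assemble_mrna(y)
    expect_identical(m1$sequence, m0$sequence)
    expect_identical(m1$cds_start, m0$cds_start)
    expect_equal(nchar(y$aptamer$sequence), s$j - s$i + 1L)
  }
  # (1, L): construct unchanged except the refolded full-length constraint
  L <- nchar(x$aptamer$sequence)
  full <- Filter(function(s) s$i == 1L && s$j == L, subs)[[1]]
  y <- rebuild_construct(x, full)
  expect_identical(y$pre_aptamer, x$pre_aptamer)
  expect_identical(y$post_aptamer, x$post_aptamer)
  expect_identical(y$aptamer$sequence, x$aptamer$sequence)
  expect_error(rebuild_construct(x, list(i = 0L, j = 3L)), "out of range")
})

test_that("grid cell (1, L) reproduces the baseline for MFE-true aptamers", {
  x <- fix_construct(11)
  L <- nchar(x$aptamer$sequence)
  sc <- scan_r_actual(x, 1.25e-6)
  expect_equal(nrow(sc$grid), L * (L + 1L) / 2L)
  cell <- sc$grid$r_actual[sc$grid$i == 1L & sc$grid$j == L]
  expect_equal(cell, sc$baseline, tolerance = 1e-9)
  expect_gte(sc$fold_span, 1)
})

test_that("select_constraint scores exact predictions perfectly", {
  grid <- expand.grid(i = 1:3, j = 1:3)
  grid <- grid[grid$i <= grid$j, ]
  fake_scan <- function(vals) {
    structure(list(grid = data.frame(i = grid$i, j = grid$j, r_actual = vals),
                   baseline = vals[1], fold_span = max(vals) / min(vals),
                   protein_conc = 1e-6, name = "fake"),
              class = "constraint_scan")
  }
  # cell-dependent predictions; riboswitches differ by known factors
  base <- c(2, 4, 8, 3, 5, 7)
  scans <- list(a = fake_scan(base), b = fake_scan(base * 3),
                c = fake_scan(base * 0.5))
  # measurements exactly equal to the predictions of cell (1,3) (row 4)
  measured <- c(a = base[4], b = base[4] * 3, c = base[4] * 0.5)
  sel <- select_constraint(scans, measured)
  expect_equal(sel$accuracy, 1.0, tolerance = 1e-12)
  expect_equal(sel$within_2fold, 1.0)
  # all cells correlate perfectly here, so the tie rule decides:
  # smallest region first, then 5'-most
  expect_equal(unname(sel$best), c(1L, 1L))

  # identical grids across cells: tie broken to smallest region, 5'-most
  flat <- lapply(list(a = 2, b = 6, c = 1), function(v) fake_scan(rep(v, 6)))
  sel2 <- select_constraint(flat, measured = c(a = 2, b = 6, c = 1))
  expect_equal(unname(sel2$best), c(1L, 1L))

  expect_error(select_constraint(scans[1], measured[1]), ">= 2")
  expect_error(select_constraint(scans, c(a = -1, b = 2, c = 3)), "> 0")
})

test_that("select_constraint recovers a generating subconstraint", {
  apt <- fix_bulged_apt()
  panel <- fix_switching_panel(apt)
  scans <- lapply(panel, scan_r_actual, protein_conc = 1.25e-6)
  names(scans) <- names(panel)
  g <- scans[[1]]$grid
  L <- nchar(apt$sequence)
  k_star <- which(g$i == 1L & g$j == L)
  pred <- vapply(scans, function(s) s$grid$r_actual, numeric(nrow(g)))
  # synthetic measurements from the model itself plus 10% lognormal noise
  set.seed(99)
  measured <- stats::setNames(pred[k_star, ] * stats::rlnorm(ncol(pred), 0, 0.1),
                              colnames(pred))
  sel <- select_constraint(scans, measured)
  # recovery up to prediction equivalence: the selected cell makes the
  # same predictions as the generating one for every riboswitch
  k_sel <- which(g$i == sel$best[["i"]] & g$j == sel$best[["j"]])
  expect_equal(unname(pred[k_sel, ]), unname(pred[k_star, ]), tolerance = 1e-9)
  expect_gt(sel$accuracy, 0.9)
})
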