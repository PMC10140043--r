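# Five-term ribosome binding model: record validation, SD search,
# final-state minimization and the dG_total decomposition.

test_that("mrna_record validates start codon and footprint room", {
  expect_silent(mrna_record("ok", paste0(strrep("A", 20), fix_cds), 21))
  expect_error(mrna_record("bad", "AAACCCAAA", 4), "codon")
  expect_error(mrna_record("short", "AUGAGCAAAG", 1), "13 nt")
  expect_error(mrna_record("oob", "AUGAGCAAAGGAGAAGAAC", 40), "within")
})

test_that("sd_hybridization reports span or a no-site sentinel", {
  h <- sd_hybridization("UAAGGAGGU")
  expect_lt(h$dg_mrna_rrna, -10)
  expect_equal(h$sd_span, c(1L, 9L))
  h2 <- sd_hybridization("AAAAAAAAA")
  expect_true(h2$no_site)
  expect_equal(h2$dg_mrna_rrna, 0)
  expect_error(sd_hybridization(""), "non-empty")
})

clean_cds <- "AUGAAUAAAAAUAAAAAA"  # no C/G outside the start codon

test_that("unstructured UTR with consensus SD has vanishing penalties", {
  # poly-A flanks neither fold against the G-rich SD nor form a stable
  # duplex with the anti-SD, so the SD placement is unambiguous
  m <- mrna_record("clean", paste0("AAAAAAA", "UAAGGAGGU", "AAAAA", clean_cds), 22)
  e <- total_binding_energy(m)
  expect_equal(e$dg_spacing, 0)
  expect_equal(e$dg_standby, 0)
  expect_equal(e$dg_initial, 0)
  expect_equal(e$dg_final, e$dg_mrna_rrna + e$dg_start, tolerance = 1e-9)
  expect_equal(e$spacing_nt, 5L)
  expect_false(e$no_sd)
})

test_that("moving the SD away from the start codon costs spacing penalty", {
  calib <- default_calib
  near <- mrna_record("near", paste0("AAAAAAAAAAA", "UAAGGAGGU", "AAAAA", clean_cds), 26)
  far <- mrna_record("far", paste0("AAAAAAA", "UAAGGAGGU", "AAAAAAAAA", clean_cds), 26)
  en <- total_binding_energy(near, NULL, calib)
  ef <- total_binding_energy(far, NULL, calib)
  expect_equal(en$spacing_nt, 5L)
  expect_equal(ef$spacing_nt, 9L)
  expect_equal(ef$dg_final - en$dg_final,
               dg_spacing_penalty(9, calib) - dg_spacing_penalty(5, calib),
               tolerance = 1e-9)
  expect_gt(ef$dg_final, en$dg_final)
})

test_that("a hairpin inside the footprint raises dG_final by its unfolding cost", {
  base <- paste0("AAAAAAA", "UAAGGAGGU", "AAAAA", clean_cds)
  # stable hairpin wholly inside the 13-nt footprint past the start codon
  hp_cds <- "AUGGGCAAAAGCCAAUAAC"
  with_hp <- paste0("AAAAAAA", "UAAGGAGGU", "AAAAA", hp_cds)
  e0 <- total_binding_energy(mrna_record("open", base, 22))
  e1 <- total_binding_energy(mrna_record("hp", with_hp, 22))
  expect_lt(e1$dg_initial, 0)        # the hairpin folds in the initial state
  expect_equal(e1$dg_final, e0$dg_final, tolerance = 1e-9)  # ribosome unfolds it
  expect_equal(e1$dg_total - e0$dg_total, -e1$dg_initial, tolerance = 1e-9)
  expect_gt(e1$dg_total, e0$dg_total)
})

test_that("dG_total equals dG_final minus dG_initial on varied inputs", {
  set.seed(7)
  for (k in 1:8) {
    utr <- random_rna(sample(15:30, 1))
    m <- mrna_record(paste0("r", k), paste0(utr, fix_cds), nchar(utr) + 1L)
    e <- total_binding_energy(m)
    expect_equal(e$dg_total, e$dg_final - e$dg_initial, tolerance = 1e-6)
    expect_lte(e$dg_mrna_rrna, 0)
    expect_lte(e$dg_start, 0)
    expect_gte(e$dg_spacing, -1e-12)
    expect_gte(e$dg_standby, -1e-12)
  }
})

test_that("final state equals a brute-force minimum over SD placements", {
  calib <- default_calib
  oracle_final <- function(m) {
    n <- nchar(m$sequence)
    codon <- substr(m$sequence, m$cds_start, m$cds_start + 2L)
    foot_end <- min(n, m$cds_start + calib$footprint_past_start - 1L)
    best <- Inf
    for (b in seq(max(1L, m$cds_start - 1L - calib$spacing_range[2]),
                  m$cds_start - 1L - calib$spacing_range[1])) {
      if (b < 1L) next
      a <- max(1L, b - (nchar(calib$anti_sd) + 2L) + 1L)
      d <- duplex_fold(substr(m$sequence, a, b), calib$anti_sd,
                       temperature = calib$temperature)
      if (d$no_site) next
      span <- a - 1L + d$query_span
      spacing <- m$cds_start - 1L - span[2]
      if (spacing < calib$spacing_range[1] || spacing > calib$spacing_range[2]) next
      con <- strsplit(strrep(".", n), "")[[1]]
      con[span[1]:foot_end] <- "x"
      outside <- fold_mfe(m$sequence, paste(con, collapse = ""),
                          temperature = calib$temperature)$dg_fold
      sb_a <- max(1L, span[1] - calib$standby_window)
      standby <- if (span[1] - sb_a >= 5L) {
        max(0, -fold_mfe(substr(m$sequence, sb_a, span[1] - 1L),
                         temperature = calib$temperature)$dg_fold)
      } else 0
      dgf <- d$energy + calib$start_codon_energies[[codon]] +
        dg_spacing_penalty(spacing, calib) + standby + outside
      best <- min(best, dgf)
    }
    best
  }
  set.seed(11)
  for (k in 1:5) {
    utr <- paste0(random_rna(10), "AGGAGG", random_rna(6))
    m <- mrna_record(paste0("o", k), paste0(utr, fix_cds), nchar(utr) + 1L)
    fin <- ribosome_final_state(m, NULL, calib)
    expect_equal(fin$dg_final, oracle_final(m), tolerance = 1e-9)
  }
})

test_that("no SD site yields a flagged sentinel, not an error", {
  m <- mrna_record("dead", paste0(strrep("C", 20), fix_cds), 21)
  e <- total_binding_energy(m)
  expect_true(e$no_sd)
  expect_equal(e$dg_mrna_rrna, 0)
})

test_that("a stabilizing hairpin 3' of the footprint leaves dG_total unchanged", {
  utr <- paste0("AAAAAAA", "UAAGGAGGU", "AAAAA")
  hp <- "GGGGCGCAAAAGCGCCCC"
  plain <- mrna_record("plain", paste0(utr, clean_cds, strrep("A", 24)), 22)
  with_hp <- mrna_record("hp3", paste0(utr, clean_cds, strrep("A", 3), hp, strrep("A", 3)), 22)
  e0 <- total_binding_energy(plain)
  e1 <- total_binding_energy(with_hp)
  expect_equal(e1$dg_total, e0$dg_total, tolerance = 1e-6)
  expect_lt(e1$dg_initial, e0$dg_initial)  # the hairpin does fold
})
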