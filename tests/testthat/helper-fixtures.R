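# Shared fixtures, built in code. Folding results are memoised inside the
# package, so reusing these across test files keeps the suite fast.

default_calib <- calibration_params()

fix_hairpin_apt <- function() toy_aptamer("hairpin", 4L, 4L, kd = 1e-8)
fix_bulged_apt <- function() toy_aptamer("bulged_hairpin", 5L, 5L, kd = 2e-8)

# CDS used throughout: starts with AUG, > 13 nt
fix_cds <- "AUGAGCAAAGGAGAAGAAC"

# consensus SD + 5 nt C spacer: C cannot pair with the anti-SD
# (ACCUCCUUA has no G), so the SD placement is unambiguous
fix_sd_cassette <- "UAAGGAGGUCCCCC"

fix_construct <- function(seed, apt = fix_bulged_apt(), pre_len = 8L,
                          post_len = 8L) {
  random_construct(apt, seed = seed, pre_len = pre_len, post_len = post_len)
}

# a panel of toy constructs with real switching (nonzero refolding /
# r_max spread), used by scan and selection tests
fix_switching_panel <- function(apt = fix_bulged_apt()) {
  seeds <- c(1L, 3L, 11L, 14L)
  xs <- lapply(seeds, function(s)
    random_construct(apt, seed = s, pre_len = 6L + (s %% 6L),
                     post_len = 4L + (s %% 9L)))
  names(xs) <- vapply(xs, `[[`, "", "name")
  xs
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
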