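simple_table <- function() {
  harmonisation_table(data.frame(
    original = c("A-type", "A", "B", "Q"),
    h0 = c("A", "A", "B", "Q"),
    h1 = c("A", "A", "B", "Q"),
    h2 = c("AB", "AB", "AB", "Q"),
    include = c(TRUE, TRUE, TRUE, FALSE)))
}

seq_of <- function(taxa, counts, age = 100) {
  pollen_sequence("S", 50, 10,
                  data.frame(age_bp = age, taxon = taxa, count = counts))
}

test_that("synonyms are summed and excluded taxa removed", {
  s <- seq_of(c("A-type", "A", "B"), c(10, 5, 3))
  h <- harmonise(s, simple_table(), "H0")
  expect_equal(setNames(h$samples$count, h$samples$taxon),
               c(A = 15, B = 3))

  s2 <- seq_of(c("A", "Q"), c(10, 7))   # Q is non-terrestrial
  h2 <- harmonise(s2, simple_table(), "H0")
  expect_equal(total_count(h2), 10)
  expect_false("Q" %in% h2$samples$taxon)
})

test_that("an identity table at H0 returns the input counts unchanged", {
  s <- seq_of(c("A", "B"), c(4, 6))
  h <- harmonise(s, simple_table(), "H0")
  expect_equal(h$samples[c("age_bp", "taxon", "count")],
               s$samples[c("age_bp", "taxon", "count")],
               ignore_attr = TRUE)
})

test_that("unmapped names error or are dropped with an audit list", {
  s <- seq_of(c("A", "Mystery"), c(4, 6))
  expect_error(harmonise(s, simple_table(), "H0"), "Mystery")
  expect_warning(h <- harmonise(s, simple_table(), "H0",
                                unmapped_policy = "drop"), "unmapped")
  expect_equal(attr(h, "unmapped"), "Mystery")
  expect_equal(total_count(h), 4)
})

test_that("included totals are conserved and richness monotone across levels", {
  ds <- generate_dataset(generator_config(seed = 5, n_sites_per_region = 2))
  seqs <- counts_from_columns(ds$counts)
  for (s in seqs[1:3]) {
    hs <- lapply(c("H0", "H1", "H2"), function(l)
      harmonise(s, ds$synonyms, l))
    totals <- vapply(hs, total_count, 0)
    expect_equal(totals[1], totals[2])
    expect_equal(totals[2], totals[3])
    rich <- vapply(hs, function(h) length(unique(h$samples$taxon)), 0L)
    expect_true(all(diff(rich) <= 0))
    # per-sample monotonicity too
    for (lv in 1:2) {
      r1 <- tapply(hs[[lv]]$samples$taxon, hs[[lv]]$samples$age_bp,
                   function(x) length(unique(x)))
      r2 <- tapply(hs[[lv + 1]]$samples$taxon, hs[[lv + 1]]$samples$age_bp,
                   function(x) length(unique(x)))
      expect_true(all(r2[names(r1)] <= r1))
    }
  }
})

test_that("harmonising twice at the same level is idempotent", {
  fx <- small_fixture()
  # identity rows for already-accepted names let the output re-enter
  ident <- as.data.frame(fx$synonyms)
  h1 <- harmonise(fx$seqs$MER_1, fx$synonyms, "H0")
  h2 <- harmonise(h1, harmonisation_table(ident), "H0")
  expect_equal(h2$samples, h1$samples, ignore_attr = TRUE)
})

test_that("richness_by_level matches a brute-force distinct-name oracle", {
  set.seed(31)
  n <- 40
  tab <- harmonisation_table(data.frame(
    original = sprintf("t%02d", 1:n),
    h0 = sprintf("h0_%02d", rep(1:20, each = 2)),
    h1 = sprintf("h1_%02d", rep(1:10, each = 4)),
    h2 = sprintf("h2_%02d", rep(1:5, each = 8)),
    include = TRUE))
  used <- sample(tab$original, 17)
  s <- seq_of(used, rep(1, length(used)))
  got <- richness_by_level(s, tab)
  idx <- match(used, tab$original)
  expect_equal(unname(got),
               c(length(unique(tab$h0[idx])), length(unique(tab$h1[idx])),
                 length(unique(tab$h2[idx]))))
  expect_true(got["n_h0"] >= got["n_h1"] && got["n_h1"] >= got["n_h2"])
  s1 <- seq_of(tab$original[1], 1)
  expect_equal(unname(richness_by_level(s1, tab)), c(1, 1, 1))
})

test_that("hierarchy violations are rejected at load", {
  expect_error(harmonisation_table(data.frame(
    original = c("x", "y"), h0 = c("A", "A"), h1 = c("P", "Q"),
    h2 = c("Z", "Z"), include = TRUE)), "hierarchy violation")
  # include flag differing within an h0 group is also a violation
  expect_error(harmonisation_table(data.frame(
    original = c("x", "y"), h0 = c("A", "A"), h1 = c("P", "P"),
    h2 = c("Z", "Z"), include = c(TRUE, FALSE))), "hierarchy violation")
})
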