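test_that("contiguity counts components like the flood-fill oracle", {
  expect_equal(type_contiguity(disc_lattice(type = 1L), "ES"),
               list(component_count = 1L, contiguous = TRUE))
  # two separated discs of the same type
  g <- matrix(0L, 20, 20)
  g[3:6, 3:6] <- 1L; g[14:17, 14:17] <- 2L
  two <- new_lattice(g, c(1L, 1L))
  expect_equal(type_contiguity(two, "ES")$component_count, 2L)
  expect_false(type_contiguity(two, "ES")$contiguous)
  expect_error(type_contiguity(two, "XEN"), "absent")

  set.seed(11)
  for (case in 1:30) {
    mask <- matrix(rbinom(144, 1, 0.5), 12, 12)
    lat <- new_lattice(mask, 1L)
    got <- type_contiguity(lat, "ES",
                           neighbourhood = 1L + case %% 2)$component_count
    expect_equal(got, oracle_components(mask, 1L + case %% 2))
  }
})

test_that("contact census matches the brute-force scan", {
  for (s in 1:10) {
    lat <- random_lattice(n = 13, n_cells = 5, seed = s)
    expect_equal(contact_lengths(lat, 2L), oracle_contacts(lat, 2L))
    expect_equal(contact_lengths(lat, 1L), oracle_contacts(lat, 1L))
  }
})

test_that("envelopment fractions: complete ring, half-half split, sum to 1", {
  ring <- ring_lattice(inner = 1L, outer = 3L)   # XEN ring around ES
  expect_equal(envelopment_fraction(ring, "XEN"), 1.0)
  expect_equal(envelopment_fraction(ring, "ES"), 0.0)

  # square block split into left/right halves: symmetric boundary share
  g <- matrix(0L, 20, 20)
  g[5:16, 5:10] <- 1L; g[5:16, 11:16] <- 2L
  half <- new_lattice(g, c(1L, 2L))
  expect_equal(envelopment_fraction(half, "ES"), 0.5)
  expect_equal(envelopment_fraction(half, "TS"), 0.5)

  for (s in 1:5) {
    lat <- random_lattice(n = 15, n_cells = 6, seed = s)
    fr <- vapply(1:3, function(t)
      tryCatch(envelopment_fraction(lat, t), error = function(e) 0),
      numeric(1))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  empty <- new_lattice(matrix(0L, 5, 5), integer(0))
  expect_error(envelopment_fraction(empty, "ES"), "empty aggregate")
})

test_that("XEN interposition flag follows the contact definition", {
  expect_true(xen_interposition(stripe_lattice(a = 1L, mid = 3L, b = 2L)))
  expect_false(xen_interposition(stripe_lattice(a = 3L, mid = 1L, b = 2L)))
  expect_false(xen_interposition(etx_lattice()))
  g <- matrix(0L, 10, 10); g[3:5, 3:5] <- 1L; g[6:8, 6:8] <- 2L
  expect_error(xen_interposition(new_lattice(g, c(1L, 2L))), "missing")
})

test_that("the sorted-configuration taxonomy enumerates exactly 16 classes", {
  tax <- configuration_taxonomy()
  expect_equal(nrow(tax), 16L)
  expect_equal(anyDuplicated(tax$label_id), 0L)
  expect_true("ETX-like" %in% tax$label_id)
  expect_equal(sum(tax$family == "xen-enveloped"), 5L)
  expect_equal(sum(tax$family == "es-enveloped"), 4L)
  expect_equal(sum(tax$family == "ts-enveloped"), 4L)
  expect_equal(sum(tax$family == "open"), 3L)
  expect_false("unsorted" %in% tax$label_id)
  expect_false("degenerate" %in% tax$label_id)
})

test_that("each of the 16 classes is recovered from a constructed lattice", {
  fixtures <- list(
    `ETX-like` = etx_lattice(),
    `env(XEN;ES|TS)` = env_fixture(3L, separated = TRUE),
    `env(XEN;ES-split)` = env_split_fixture(3L, "first"),
    `env(XEN;TS-split)` = env_split_fixture(3L, "second"),
    `env(XEN;both-split)` = env_split_fixture(3L, "both"),
    `env(ES;TS,XEN)` = env_fixture(1L),
    `env(ES;TS-split)` = env_split_fixture(1L, "first"),
    `env(ES;XEN-split)` = env_split_fixture(1L, "second"),
    `env(ES;both-split)` = env_split_fixture(1L, "both"),
    `env(TS;ES,XEN)` = env_fixture(2L),
    `env(TS;ES-split)` = env_split_fixture(2L, "first"),
    `env(TS;XEN-split)` = env_split_fixture(2L, "second"),
    `env(TS;both-split)` = env_split_fixture(2L, "both"),
    `open(adjacent)` = triangle_lattice(),
    `open(separated)` = open_stripe_fixture(mid = 3L),
    `open(one-split)` = open_stripe_fixture(mid = 3L, split_first = TRUE)
  )
  expect_setequal(names(fixtures), configuration_taxonomy()$label_id)
  for (lab in names(fixtures)) {
    expect_equal(classify(fixtures[[lab]])$label_id, lab, label = lab)
  }
  # the open interposed arrangement carries the interposition flag
  expect_true(classify(open_stripe_fixture(mid = 3L))$interposition)
  expect_true(classify(env_fixture(3L, separated = TRUE))$interposition)
})

test_that("classification is invariant under symmetry and id relabelling", {
  lats <- list(etx_lattice(), onion_lattice(), triangle_lattice(),
               stripe_lattice(a = 1L, mid = 3L, b = 2L),
               env_fixture(2L, separated = TRUE))
  for (lat in lats) {
    ref <- classify(lat)$label_id
    expect_equal(classify(rot90_lattice(lat))$label_id, ref)
    expect_equal(classify(mirror_lattice(lat))$label_id, ref)
  }
  # permute cell ids within types: split the ES half-disc of the ETX
  # fixture into two ES cells, then swap their ids
  lat <- etx_lattice()
  g <- lat$grid
  es <- which(g == 1L, arr.ind = TRUE)
  top <- es[es[, 1] < mean(es[, 1]), ]
  g[top] <- 4L
  split1 <- new_lattice(g, c(1L, 2L, 3L, 1L))
  g2 <- g
  g2[g == 1L] <- 4L; g2[g == 4L] <- 1L
  split2 <- new_lattice(g2, c(1L, 2L, 3L, 1L))
  expect_equal(classify(split1)$label_id, classify(split2)$label_id)
  expect_equal(classify(split1)$label_id, "ETX-like")
})

test_that("degenerate and unsorted inputs are labelled, never silent", {
  g <- matrix(0L, 12, 12); g[4:9, 4:9] <- 1L
  expect_equal(classify(new_lattice(g, 1L))$label_id, "degenerate")
  cfg <- default_config()
  mixed <- initialize_aggregate(c(ES = 6, TS = 14, XEN = 5), cfg, seed = 1)
  expect_equal(classify(mixed)$label_id, "unsorted")
})

test_that("ensemble summaries group strictly-below-threshold labels", {
  s <- summarize_ensemble(rep("ETX-like", 10))
  expect_equal(unname(s$freq), 1)
  expect_equal(s$n_runs, 10L)
  # boundary case: 1/20 = 5% is NOT below a 5% threshold
  s2 <- summarize_ensemble(c(rep("A", 19), "B"), group_threshold = 0.05)
  expect_true("B" %in% names(s2$grouped))
  # 1/25 = 4% is grouped
  s3 <- summarize_ensemble(c(rep("A", 24), "B"), group_threshold = 0.05)
  expect_false("B" %in% names(s3$grouped))
  expect_equal(sum(s3$counts), 25L)
  expect_true("B" %in% names(s3$counts))  # raw counts retained
})
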