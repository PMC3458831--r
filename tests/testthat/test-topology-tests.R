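test_that("monophyly is exact bipartition existence", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_false(is_monophyletic(ape::read.tree(text = "((A,C),(B,D));"), c("A", "B")))

  expect_error(is_monophyletic(tr, c("A", "Z")), "missing.*Z")
  expect_error(is_monophyletic(tr, "A"), "at least 2")

  # a polytomy covering the group plus another taxon is NOT monophyly
  poly <- ape::read.tree(text = "((A,B,C),(D,E));")
  expect_false(is_monophyletic(poly, c("A", "B")))
  expect_true(is_monophyletic(poly, c("A", "B", "C")))
})

test_that("monophyly agrees with the edge-enumeration oracle on random trees", {
  set.seed(61)
  for (i in 1:20) {
    tr <- simulate_yule_tree(8)
    labs <- tr$tip.label
    splits <- oracle_splits(tr)
    for (size in 2:6) {
      for (j in 1:5) {
        grp <- sample(labs, size)
        expect_equal(
          is_monophyletic(tr, grp),
          oracle_monophyletic(tr, grp, splits),
          info = paste(ape::write.tree(tr), paste(grp, collapse = ","))
        )
      }
    }
  }
})

test_that("outgroup-rooted monophyly matches the rooted reading", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),OUT);")
  expect_true(is_monophyletic(tr, c("A", "B"), outgroup = "OUT"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D"), outgroup = "OUT"))
  expect_false(is_monophyletic(tr, c("B", "C"), outgroup = "OUT"))
  expect_error(is_monophyletic(tr, c("A", "OUT"), outgroup = "OUT"), "overlap")
})

test_that("constraints validate their groups, backbone and outgroup", {
  expect_error(constraint(list(G1 = c("A", "B"), G2 = c("B", "C"))), "disjoint")
  expect_error(constraint(list(G1 = character())), "empty")
  expect_error(
    constraint(list(G1 = c("A", "B")), backbone = "((G1,G9));"),
    "G9"
  )
  expect_error(
    constraint(list(G1 = c("A", "B")), outgroup = "A"),
    "overlap"
  )
})

test_that("backbone constraints expand group bipartitions correctly", {
  cons <- constraint(
    list(G1 = c("A", "B"), G2 = "C", G3 = c("D", "E")),
    backbone = "((G1,G2),G3);"
  )
  expect_true(constraint_consistent(ape::read.tree(text = "(((A,B),C),(D,E));"), cons))
  # G1 not monophyletic
  expect_false(constraint_consistent(ape::read.tree(text = "(((A,C),B),(D,E));"), cons))
  # groups fine but backbone split {A,B,C}|{D,E} absent
  expect_false(constraint_consistent(ape::read.tree(text = "(((A,B),D),(C,E));"), cons))
  # ungrouped taxa are ignored by restriction
  with_extra <- ape::read.tree(text = "((((A,B),C),(D,E)),(X,Y));")
  expect_true(constraint_consistent(with_extra, cons))

  # single group without backbone reduces to plain monophyly
  single <- constraint(list(G = c("A", "B")))
  tr <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(constraint_consistent(tr, single), is_monophyletic(tr, c("A", "B")))
  tr2 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(constraint_consistent(tr2, single), is_monophyletic(tr2, c("A", "B")))
})

test_that("an outgroup makes the backbone reading rooted", {
  cons <- constraint(
    list(G1 = c("A", "B"), G2 = c("C", "D"), G3 = c("E", "F")),
    backbone = "((G1,G2),G3);",
    outgroup = "OUT"
  )
  yes <- ape::read.tree(text = "((((A,B),(C,D)),(E,F)),OUT);")
  expect_true(constraint_consistent(yes, cons))
  # same unrooted topology among groups but (G1,G2) not a rooted clade
  no <- ape::read.tree(text = "((((E,F),(C,D)),(A,B)),OUT);")
  expect_false(constraint_consistent(no, cons))
})

test_that("posterior frequency counts trees and rounds the percentage half-up", {
  base <- simulate_yule_tree(8, seed = 71)
  clade <- paste0("t", 1:3)
  cons <- constraint(list(focal = clade), name = "focal")

  ts <- simulate_tree_set(base, clade, f = 1, total = 20, seed = 3)
  res <- posterior_frequency(ts, cons)
  expect_equal(res$n_consistent, 20)
  expect_equal(res$pp_display, 100)

  ts2 <- simulate_tree_set(base, clade, f = 0.25, total = 40, mode = "deterministic", seed = 5)
  res2 <- posterior_frequency(ts2, cons)
  expect_equal(res2$n_consistent, 10)
  expect_equal(res2$pp, 25)

  # display rounding is half-up on the exact rational
  expect_equal(phylomrm:::percent_half_up(33, 12000), 0.28)
  expect_equal(phylomrm:::percent_half_up(484, 12000), 4.03)
  expect_equal(phylomrm:::percent_half_up(1, 3), 33.33)
  expect_equal(phylomrm:::percent_half_up(0, 5), 0)
  expect_equal(phylomrm:::percent_half_up(5, 5), 100)
})

test_that("posterior frequency is order-invariant and monotone in constraint size", {
  base <- simulate_yule_tree(10, seed = 73)
  cons <- constraint(list(focal = paste0("t", 1:4)), name = "f")
  ts <- simulate_tree_set(base, paste0("t", 1:4), f = 0.5, total = 20, seed = 7)

  shuffled <- tree_set(sample(unclass(ts$trees)), run = "x")
  expect_equal(
    posterior_frequency(ts, cons)$n_consistent,
    posterior_frequency(shuffled, cons)$n_consistent
  )

  # adding groups (keeping taxon coverage) can only keep or reduce the count
  set.seed(79)
  for (i in 1:5) {
    g2 <- sample(paste0("t", 5:10), 3)
    g3 <- setdiff(paste0("t", 5:10), g2)
    wider <- constraint(
      list(focal = paste0("t", 1:4), extra = g2, rest = g3),
      name = "f2"
    )
    expect_lte(
      posterior_frequency(ts, wider)$n_consistent,
      posterior_frequency(ts, cons)$n_consistent
    )
  }
})

test_that("constraints round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "H1:",
    "  groups:",
    "    G1: [A, B]",
    "    G2: [C]",
    "    G3: [D, E]",
    "  backbone: \"((G1,G2),G3);\"",
    "mono:",
    "  groups:",
    "    focal: [A, B, C]",
    "  outgroup: [OUT]"
  ), f)
  cs <- read_constraints(f)
  expect_named(cs, c("H1", "mono"))
  expect_equal(cs$H1$groups$G3, c("D", "E"))
  expect_s3_class(cs$H1$backbone, "phylo")
  expect_equal(cs$mono$outgroup, "OUT")

  res <- posterior_frequency(
    list(ape::read.tree(text = "(((A,B),C),(D,E));")),
    cs["H1"]
  )
  expect_equal(res$hypothesis, "H1")
  expect_equal(res$n_consistent, 1)
})
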