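test_that("SMILES parsing yields correct composition and descriptors", {
  benzene <- parse_molecule("c1ccccc1", "benzene")
  expect_equal(benzene$n_carbon, 6)
  expect_equal(benzene$n_hbd, 0)

  ethanol <- parse_molecule("CCO", "ethanol")
  expect_equal(ethanol$n_hba, 1)
  expect_equal(ethanol$n_hbd, 1)
  expect_equal(ethanol$n_carbon, 2)
  expect_gt(ethanol$mol_weight, 0)
})

test_that("unparseable SMILES raises an error naming the molecule", {
  expect_error(parse_molecule("C1CC", "ring-open"), "ring-open")
  expect_error(parse_molecule("", "blank"), "blank")
})

test_that("salt stripping keeps the largest covalent fragment", {
  rec <- parse_molecule("CC(=O)[O-].[Na+]", "sodium-acetate")
  expect_equal(rec$n_carbon, 2)
  expect_false(grepl("Na", rec$smiles))
})

test_that("fingerprints are deterministic across SMILES variants", {
  for (scheme in fingerprint_schemes()) {
    fp1 <- compute_fingerprint(parse_molecule("c1ccccc1O", "phenol-a"), scheme)
    fp2 <- compute_fingerprint(parse_molecule("Oc1ccccc1", "phenol-b"), scheme)
    expect_identical(fp1$values, fp2$values)
  }
})

test_that("structural keys distinguish heteroaromatic substitution", {
  fb <- compute_fingerprint(parse_molecule("c1ccccc1", "benzene"),
                            "structural-keys-166")
  fpyr <- compute_fingerprint(parse_molecule("c1ccncc1", "pyridine"),
                              "structural-keys-166")
  expect_equal(fb$length, 166L)
  expect_true(all(fb$values %in% 0:1))
  expect_false(identical(fb$values, fpyr$values))
})

test_that("count fingerprints dominate binary ones on repeated environments", {
  # linear pentane: interior CH2 environments repeat
  pentane <- parse_molecule("CCCCC", "pentane")
  fpc <- compute_fingerprint(pentane, "circular-count-r2")
  fpb <- compute_fingerprint(pentane, "circular-binary-r2")
  expect_gte(sum(fpc$values), sum(fpb$values))
  expect_gt(sum(fpc$values), sum(fpc$values > 0))  # repeats present
  expect_true(all(fpb$values %in% 0:1))
})

test_that("fixed-length contract is enforced", {
  mol <- parse_molecule("CCO", "ethanol")
  expect_error(compute_fingerprint(mol, "daylight"), "unsupported")
  expect_error(compute_fingerprint(mol, "structural-keys-166", length = 512),
               "166")
  fp <- compute_fingerprint(mol, "circular-binary-r2", length = 256)
  expect_length(fp$values, 256)
})

test_that("tanimoto reproduces hand-computed values", {
  expect_equal(tanimoto(make_fp(c(0, 1, 1, 0, 0), length = 5),
                        make_fp(c(0, 0, 1, 1, 0), length = 5)), 1 / 3)
  expect_equal(tanimoto(make_fp(c(2, 0, 3)), make_fp(c(1, 1, 3))), 4 / 6)
  a <- make_fp(c(1, 1, 0, 1))
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(make_fp(c(1, 1, 0, 0)), make_fp(c(0, 0, 1, 1))), 0.0)
})

test_that("tanimoto rejects mismatched fingerprints and flags empty pairs", {
  a <- make_fp(c(1, 0), scheme = "circular-binary-r2")
  b <- make_fp(c(1, 0), scheme = "path-hashed-binary")
  expect_error(tanimoto(a, b), "mismatch")
  expect_error(tanimoto(make_fp(c(1, 0), length = 2),
                        make_fp(c(1, 0, 0), length = 3)), "mismatch")
  expect_warning(z <- tanimoto(make_fp(c(0, 0)), make_fp(c(0, 0))), "empty")
  expect_equal(z, 0)
})

test_that("tanimoto satisfies symmetry, bounds, and the set oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:32, 1)
    a <- make_fp(rbinom(n, 1, 0.4), length = n)
    b <- make_fp(rbinom(n, 1, 0.4), length = n)
    if (sum(a$values) + sum(b$values) == 0) next
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, tanimoto_set_oracle(a$values, b$values))
  }
})

test_that("count-Tanimoto reduces to binary Tanimoto on 0/1 vectors", {
  set.seed(12)
  for (rep in 1:25) {
    v1 <- rbinom(16, 1, 0.5); v2 <- rbinom(16, 1, 0.5)
    if (sum(v1) + sum(v2) == 0) next
    expect_identical(tanimoto(make_fp(v1), make_fp(v2)),
                     tanimoto_set_oracle(v1, v2))
  }
})

test_that("pair similarity tables preserve order, symmetry and self-pairs", {
  mols <- list(
    e = parse_molecule("CCO", "ethanol"),
    p = parse_molecule("CCCO", "propanol"),
    b = parse_molecule("c1ccccc1", "benzene")
  )
  pairs <- list(p1 = list(mols$e, mols$p),
                p2 = list(mols$e, mols$b),
                p3 = list(mols$p, mols$p))
  schemes <- c("circular-binary-r2", "structural-keys-166")
  tab <- pair_similarity_table(pairs, schemes = schemes)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$pair_id, c("p1", "p2", "p3"))
  expect_true(all(schemes %in% names(tab)))
  # self-pair similarity 1 under every scheme
  expect_equal(unlist(tab[3, schemes]), c(1, 1), ignore_attr = TRUE)
  # symmetry under argument swap
  rev_tab <- pair_similarity_table(list(p1 = list(mols$p, mols$e)),
                                   schemes = schemes)
  expect_equal(unlist(rev_tab[1, schemes]), unlist(tab[1, schemes]),
               ignore_attr = TRUE)
  expect_error(pair_similarity_table(list()), "no molecule pairs")
})
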