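# Descriptors, screens, fingerprints, scaffolds, enrichment, metrics.

test_that("property records are sane on hand-checkable molecules", {
  p <- compute_properties(c("CCO", "C", "c1ccccc1"))
  expect_equal(p$hbd, c(1L, 0L, 0L))
  expect_equal(p$hba, c(1L, 0L, 0L))
  expect_equal(p$tpsa[2], 0)
  expect_equal(p$mw[1], 46.07, tolerance = 0.01)
  expect_true(all(p$mw > 0))
  expect_match(attr(p, "logp_estimator"), "logP")
  expect_error(compute_properties("C1CC"), "invalid")
})

test_that("rule-of-five boundaries are inclusive", {
  props <- data.frame(mw = c(500, 610, 180, 400),
                      logp = c(5, 1, 1.3, 6),
                      hbd = c(5, 1, 1, 1),
                      hba = c(10, 2, 4, 2))
  expect_equal(ro5_compliant(props), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ro5_compliant(props, max_violations = 1),
               c(TRUE, TRUE, TRUE, TRUE))
})

test_that("PAINS flags match direct substructure checks", {
  smis <- c("CCO",                      # clean
            "O=C1C=CC(=O)C=C1",         # para-quinone
            "Oc1ccccc1O",               # catechol
            "S=C1NC(=O)CS1",            # rhodanine
            "CCCC(=O)NC")               # clean amide
  fl <- pains_flag(smis)
  expect_equal(fl, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # every bundled pattern compiles
  catal <- pains_catalog()
  expect_true(nrow(catal) >= 20L)
  for (i in seq_len(nrow(catal))) {
    expect_silent(inertforge:::smarts_pattern(catal$smarts[i]))
  }
})

test_that("fingerprints are canonical-structure invariants", {
  fp <- ecfp(c("CCO", "OCC", "c1ccccc1", "CCO"))
  expect_equal(dim(fp), c(4L, 1024L))
  expect_equal(fp[1, ], fp[2, ])
  expect_equal(fp[1, ], fp[4, ])
  expect_false(all(fp[1, ] == fp[3, ]))
  expect_equal(attr(fp, "radius"), 2L)
})

test_that("tanimoto follows the bit-set definition", {
  a <- integer(16); a[c(1, 2, 3)] <- 1L
  b <- integer(16); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, integer(16) + c(rep(0L, 8), 1L, rep(0L, 7))), 0)
  expect_equal(tanimoto(integer(16), integer(16)), 0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, b[1:8]), "mismatch")
})

test_that("nearest-neighbor Tc matches the brute-force oracle", {
  set.seed(12)
  qm <- matrix(rbinom(10 * 64, 1, 0.2), 10, 64)
  rm_ <- matrix(rbinom(10 * 64, 1, 0.2), 10, 64)
  fast <- nearest_neighbor_tc(qm, rm_)
  slow <- vapply(seq_len(nrow(qm)), function(i) {
    max(vapply(seq_len(nrow(rm_)), function(j) tanimoto(qm[i, ], rm_[j, ]),
               numeric(1)))
  }, numeric(1))
  expect_equal(fast, slow)
  # query identical to a reference member
  expect_equal(nearest_neighbor_tc(rm_[3, , drop = FALSE], rm_), 1)
  # single-reference case reduces to plain tanimoto
  expect_equal(nearest_neighbor_tc(qm, rm_[1, , drop = FALSE]),
               apply(qm, 1, tanimoto, b = rm_[1, ]))
  expect_error(nearest_neighbor_tc("CCO", character()), "empty")
})

test_that("Murcko scaffolds agree with an independent toolkit", {
  smis <- c("CCc1ccccc1", "O=C(O)c1ccc(N)cc1", "C1CCCCC1Cc1ccccc1",
            "CC(C)N1CCN(CC1)c1ccccn1", "O=C(Nc1ccccc1)c1cccs1")
  ours <- murcko_scaffold(smis)
  py <- run_python(c(
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    sprintf("smis = %s",
            paste0("['", paste(smis, collapse = "','"), "']")),
    "for s in smis:",
    "    m = Chem.MolFromSmiles(s)",
    "    sc = MurckoScaffold.GetScaffoldForMol(m)",
    "    print(Chem.MolToSmiles(sc))"))
  # compare as structures: canonicalize both sides with the same toolkit
  expect_equal(canonicalize_smiles(ours), canonicalize_smiles(py))
})

test_that("acyclic molecules have no scaffold", {
  expect_equal(murcko_scaffold(c("CCO", "CCCCC", "C")), c("", "", ""))
})

test_that("BRICS fragmentation matches the reference rule set", {
  smis <- c("CC(=O)Nc1ccccc1", "c1ccccc1OC", "CCO",
            "O=C(Nc1ccccc1)c1cccs1")
  ours <- brics_fragments(smis)
  py <- run_python(c(
    "from rdkit import Chem",
    "from rdkit.Chem import BRICS",
    sprintf("smis = %s",
            paste0("['", paste(smis, collapse = "','"), "']")),
    "for s in smis:",
    "    m = Chem.MolFromSmiles(s)",
    "    pieces = Chem.GetMolFrags(BRICS.BreakBRICSBonds(m), asMols=True)",
    "    frs = []",
    "    for p in pieces:",
    "        q = Chem.DeleteSubstructs(p, Chem.MolFromSmarts('[#0]'))",
    "        frs.append(Chem.MolToSmiles(q))",
    "    print(';'.join(sorted(frs)))"))
  ref <- strsplit(py, ";", fixed = TRUE)
  for (i in seq_along(smis)) {
    ours_can <- sort(canonicalize_smiles(ours[[i]]))
    ref_can <- sort(canonicalize_smiles(ref[[i]]))
    expect_equal(ours_can, ref_can, info = smis[i])
  }
})

test_that("scaffold enrichment flags a strongly skewed scaffold", {
  withA <- "CCc1ccccc1"; withB <- "CC1CCNCC1"
  set_a <- c(rep(withA, 90), rep(withB, 10))
  set_b <- c(rep(withA, 10), rep(withB, 90))
  enr <- scaffold_enrichment(set_a, set_b)
  benz <- enr[enr$scaffold == murcko_scaffold(withA), ]
  # oracle: direct chi-squared formula on the 2x2 table
  tab <- matrix(c(90, 10, 10, 90), 2)
  expect_equal(benz$chi2, unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic))
  expect_equal(benz$enriched_in, "A")
  pip <- enr[enr$scaffold == murcko_scaffold(withB), ]
  expect_equal(pip$enriched_in, "B")

  # identical sets: nothing flagged
  none <- scaffold_enrichment(set_a, set_a)
  expect_true(all(is.na(none$enriched_in)))
  expect_true(all(none$chi2 == 0))

  # degenerate margin: scaffold present everywhere
  deg <- scaffold_enrichment(rep(withA, 5), rep(withA, 7))
  expect_true(all(deg$chi2 == 0) && all(is.na(deg$enriched_in)))

  # swapping the sets flips the enrichment direction
  sw <- scaffold_enrichment(set_b, set_a)
  expect_equal(sw$enriched_in[sw$scaffold == benz$scaffold], "B")
})

test_that("MCC and balanced accuracy match their closed forms", {
  expect_equal(mcc(confusion_counts(50, 50, 0, 0)), 1)
  expect_equal(mcc(confusion_counts(25, 25, 25, 25)), 0)
  expect_equal(mcc(confusion_counts(6, 3, 1, 2)), 16 / sqrt(1120))
  expect_equal(round(mcc(confusion_counts(6, 3, 1, 2)), 4), 0.4781)
  expect_equal(mcc(confusion_counts(0, 10, 0, 5)), 0)  # degenerate -> 0

  expect_equal(balanced_accuracy(confusion_counts(50, 50, 0, 0)), 1)
  expect_equal(balanced_accuracy(confusion_counts(6, 3, 1, 2)), 0.75)
  expect_equal(balanced_accuracy(confusion_counts(10, 0, 10, 0)), 0.5)
  expect_error(balanced_accuracy(confusion_counts(0, 5, 5, 0)), "class")

  # label inversion flips the MCC sign
  set.seed(9)
  for (k in 1:20) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                           sample(0:20, 1), sample(0:20, 1))
    inv <- confusion_counts(cc$fn, cc$fp, cc$tn, cc$tp)
    expect_equal(mcc(inv), -mcc(cc), tolerance = 1e-12)
  }
})

test_that("confusion metrics agree with label-vector recomputation", {
  set.seed(14)
  for (k in 1:200) {
    n <- sample(4:40, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    cc <- confusion_from_labels(truth, pred)
    tp <- sum(truth & pred); tn <- sum(!truth & !pred)
    fp <- sum(!truth & pred); fn <- sum(truth & !pred)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    m_ref <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    expect_equal(mcc(cc), m_ref)
    if (tp + fn >= 1 && tn + fp >= 1) {
      expect_equal(balanced_accuracy(cc),
                   (tp / (tp + fn) + tn / (tn + fp)) / 2)
    }
  }
})
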