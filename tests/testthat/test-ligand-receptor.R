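test_that("regulated-gene selection applies the adjusted-p and direction filters", {
  empty <- data.frame(gene = character(), log2fc = numeric(), padj = numeric())
  expect_length(select_regulated_genes(empty), 0L)

  de <- data.frame(gene = c("A", "B", "C", "D", "E"),
                   log2fc = c(2, -1.5, 0.5, 4, -3),
                   padj = c(0.01, 0.2, 0.001, 0.04, 0.03))
  expect_setequal(select_regulated_genes(de, direction = "up"), c("A", "C", "D"))
  expect_setequal(select_regulated_genes(de, direction = "down"), "E")
  expect_setequal(select_regulated_genes(de, direction = "both"),
                  c("A", "C", "D", "E"))
  # volcano convention: log2FC cutoff 3 keeps only >8-fold genes
  expect_setequal(select_regulated_genes(de, direction = "up",
                                         min_abs_log2fc = 3), "D")
  expect_equal(log2fc_to_fold(3), 8)
  expect_error(select_regulated_genes(de[, 1:2]), "columns")
})

test_that("pair matching requires every receptor subunit above threshold", {
  db <- default_lr_database()
  receiver <- c(Il6ra = 2, Il6st = 5, Ccr2 = 1)
  m <- match_ligand_receptor(c("Il6", "Ccl2", "Lif"), db, receiver)
  expect_setequal(m$ligand, c("Il6", "Ccl2"))  # Lif needs Lifr, absent
  expect_equal(m$min_subunit_expr[m$ligand == "Il6"], 2)

  # no receptors expressed -> no matches
  expect_equal(nrow(match_ligand_receptor(c("Il6", "Ccl2"), db,
                                          c(Gapdh = 10))), 0L)
  # a subunit at exactly the threshold is NOT expressed (strict >)
  recv <- c(Il6ra = 0.5, Il6st = 5)
  expect_equal(nrow(match_ligand_receptor("Il6", db, recv,
                                          expr_threshold = 0.5)), 0L)
  expect_equal(nrow(match_ligand_receptor("Il6", db, recv,
                                          expr_threshold = 0.49)), 1L)
})

test_that("matching equals the brute-force nested-loop join on random instances", {
  set.seed(14)
  for (rep in 1:5) {
    n_pairs <- sample(20:100, 1)
    genes <- sprintf("L%03d", 1:60)
    rgenes <- sprintf("R%03d", 1:50)
    receptors <- lapply(seq_len(n_pairs), function(i)
      sample(rgenes, sample(1:3, 1)))
    key <- paste(sample(genes, n_pairs, TRUE),
                 vapply(receptors, function(r) paste(sort(r), collapse = ";"), ""))
    keep <- !duplicated(key)
    db <- lr_database(ligand = sub(" .*", "", key[keep]),
                      receptors = receptors[keep],
                      family = sample(c("ECM", "cytokine", "other"),
                                      sum(keep), TRUE))
    ligands <- sample(genes, 25)
    receiver <- setNames(round(rexp(35), 2), sample(rgenes, 35))
    thr <- sample(c(0, 0.5), 1)
    got <- match_ligand_receptor(ligands, db, receiver, expr_threshold = thr)
    want <- brute_lr_join(ligands, db, receiver, thr)
    expect_equal(which(paste(db$ligand, vapply(db$receptors, paste, "",
                                               collapse = ";")) %in%
                         paste(got$ligand, vapply(got$receptors, paste, "",
                                                  collapse = ";"))),
                 sort(want))
    expect_equal(nrow(got), length(want))
  }
})

test_that("database construction rejects malformed input", {
  expect_error(lr_database("Il6", "Il6ra;Il6st", "potion"), "unknown family")
  expect_error(lr_database(c("Il6", "Il6"), c("Il6ra;Il6st", "Il6st;Il6ra"),
                           c("cytokine", "cytokine")), "duplicate")
  expect_error(lr_database("Il6", list(character()), "cytokine"),
               "at least one receptor")
})

test_that("communication scores multiply sender by min-subunit receiver expression", {
  db <- lr_database("LigA", "RecB", "cytokine")
  sender <- c(LigA = 2)
  receiver <- c(RecB = 3)
  m <- match_ligand_receptor("LigA", db, receiver)
  sc <- communication_scores(sender, receiver, m, scaling = "none")
  expect_equal(sc$score, 6)
  expect_equal(sc$family, "cytokine")
  expect_equal(attr(sc, "contributions")$contribution, 6)

  # zero matched pairs -> zero rows
  sc0 <- communication_scores(sender, receiver, m[0, ], scaling = "none")
  expect_equal(nrow(sc0), 0L)

  # multi-subunit: the weakest chain limits the contribution
  db2 <- lr_database("LigA", "R1;R2", "ECM")
  recv2 <- c(R1 = 10, R2 = 0.5)
  m2 <- match_ligand_receptor("LigA", db2, recv2)
  sc2 <- communication_scores(sender, recv2, m2, scaling = "none")
  expect_equal(sc2$score, 2 * 0.5)

  expect_error(communication_scores(c(Other = 1), receiver, m,
                                    scaling = "none"), "absent from the sender")
})

test_that("min-max scaled scores are invariant to global expression rescaling", {
  db <- default_lr_database()
  profiles <- simulate_receiver_profiles(seed = 3L)
  de <- simulate_de_table(seed = 3L)
  sender <- setNames(de$mean_injured, de$gene)
  recv <- profiles[, "nociceptor"]
  m <- match_ligand_receptor(select_regulated_genes(de, direction = "up"),
                             db, recv)
  panel <- expression_panel(profiles, sender = sender)
  s1 <- communication_scores(sender, recv, m, panel = panel)
  expect_true(any(s1$score > 0))  # scaling must not degenerate to zero
  s2 <- communication_scores(sender * 10, recv * 10, m, panel = panel * 10)
  expect_equal(s1$score, s2$score)
  # row-order invariance
  perm <- sample(nrow(m))
  s3 <- communication_scores(sender, recv, m[perm, ], panel = panel)
  expect_equal(s3[order(s3$family), "score"], s1[order(s1$family), "score"])
  # adding a matched pair never decreases any family score
  sender2 <- c(sender, Tgfb1 = 5)
  panel2 <- expression_panel(profiles, sender = sender2)
  extra <- match_ligand_receptor("Tgfb1", db, recv)
  expect_equal(nrow(extra), 1L)
  s1b <- communication_scores(sender2, recv, m, panel = panel2)
  s4 <- communication_scores(sender2, recv, rbind(m, extra), panel = panel2)
  for (f in s1b$family)
    expect_gte(s4$score[s4$family == f], s1b$score[s1b$family == f])
  expect_true(all(setdiff(s4$family, s1b$family) %in% extra$family))
})

test_that("interaction-count comparison equals the hypergeometric tail sum", {
  r <- compare_interaction_counts(10, 30, 100)
  expect_equal(r$p_value, fisher_two_sided_oracle(10, 30, 100))
  expect_equal(r$direction, "post > pre")
  expect_equal(compare_interaction_counts(12, 12, 50)$p_value, 1)
  expect_equal(compare_interaction_counts(12, 12, 50)$direction, "no change")
  expect_error(compare_interaction_counts(60, 10, 50), "universe")
})

test_that("synthetic DE and receiver tables enable more interactions after injury", {
  de <- simulate_de_table(seed = 7L)
  up <- select_regulated_genes(de, direction = "up")
  expect_true(all(c("Il6", "Lif", "Clcf1", "Ccl2", "Ngf", "Tnc", "Spp1",
                    "Mmp9") %in% up))
  db <- default_lr_database()
  profiles <- simulate_receiver_profiles(seed = 7L)
  for (rc in colnames(profiles)) {
    m <- match_ligand_receptor(up, db, profiles[, rc])
    expect_gt(nrow(m), 0)
    # gp130 cytokine signalling is available wherever Il6st partners exist
    if (all(c("Il6ra", "Il6st") %in% rownames(profiles)) &&
        all(profiles[c("Il6ra", "Il6st"), rc] > 0))
      expect_true("Il6" %in% m$ligand)
  }
})
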