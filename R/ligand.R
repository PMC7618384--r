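#' Linear fold change at a log2 fold-change cutoff
#'
#' The volcano-plot filter convention: a log2 fold-change cutoff of 3
#' corresponds to an eightfold difference versus control.
#'
#' @param log2fc log2 fold change(s).
#' @return `2^log2fc`.
#' @export
log2fc_to_fold <- function(log2fc) 2^log2fc

.lr_families <- c("ECM", "cytokine", "growth factor", "adhesion", "chemokine",
                  "other")

#' Select significantly regulated genes from a DE table
#'
#' @param de data.frame with columns `gene`, `log2fc`, `padj` (a DESeq2-style
#'   results table; the table is consumed, never recomputed here).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param direction `"up"`, `"down"` or `"both"` (sign of `log2fc`).
#' @param min_abs_log2fc additional magnitude filter; e.g. 3 keeps only genes
#'   regulated more than eightfold.
#' @return character vector of gene symbols (possibly empty).
#' @export
select_regulated_genes <- function(de, alpha = 0.05,
                                   direction = c("up", "down", "both"),
                                   min_abs_log2fc = 0) {
  direction <- match.arg(direction)
  if (!all(c("gene", "log2fc", "padj") %in% names(de)))
    stop("DE table needs columns gene, log2fc, padj", call. = FALSE)
  if (anyDuplicated(de$gene)) stop("duplicate gene symbols in DE table", call. = FALSE)
  keep <- !is.na(de$padj) & de$padj < alpha & abs(de$log2fc) > min_abs_log2fc
  keep <- keep & switch(direction,
                        up = de$log2fc > 0,
                        down = de$log2fc < 0,
                        both = TRUE)
  as.character(de$gene[keep])
}

#' Construct a ligand-receptor pair database
#'
#' @param ligand character vector of ligand gene symbols.
#' @param receptors receptor subunit genes per pair: a list of character
#'   vectors, or a character vector of semicolon-joined symbols
#'   (`"Il6ra;Il6st"`). Multi-subunit receptors require all chains.
#' @param family interaction family per pair, one of ECM, cytokine,
#'   growth factor, adhesion, chemokine, other.
#' @param source free-text provenance tag per pair.
#' @return data.frame of class `lr_database` with list-column `receptors`.
#' @export
lr_database <- function(ligand, receptors, family, source = "curated") {
  if (is.character(receptors)) receptors <- strsplit(receptors, ";", fixed = TRUE)
  stopifnot(length(ligand) == length(receptors), length(family) == length(ligand))
  if (any(lengths(receptors) < 1L))
    stop("every pair needs at least one receptor subunit", call. = FALSE)
  bad <- setdiff(family, .lr_families)
  if (length(bad)) stop("unknown family: ", paste(unique(bad), collapse = ", "),
                        "; allowed: ", paste(.lr_families, collapse = ", "),
                        call. = FALSE)
  key <- paste(ligand, vapply(receptors, function(r) paste(sort(r), collapse = ";"), ""))
  if (anyDuplicated(key)) stop("duplicate (ligand, receptor-set) rows", call. = FALSE)
  db <- data.frame(ligand = as.character(ligand), family = as.character(family),
                   source = rep_len(as.character(source), length(ligand)))
  db$receptors <- receptors
  class(db) <- c("lr_database", "data.frame")
  db
}

#' Match regulated ligands against receptor expression in a receiver
#'
#' A pair matches iff its ligand is in `ligands` and every receptor subunit
#' has receiver expression strictly above `expr_threshold` (all chains of a
#' multi-subunit receptor must be present for signalling).
#'
#' @param ligands character vector of (typically injury-regulated) sender
#'   ligand genes.
#' @param db an [lr_database()].
#' @param receiver named numeric vector of non-negative expression values for
#'   one receiver population (genes absent from the vector count as 0).
#' @param expr_threshold receptor-expression cutoff (default 0: any positive
#'   expression counts as expressed).
#' @return the matching rows of `db`, with an added `min_subunit_expr` column.
#' @export
match_ligand_receptor <- function(ligands, db, receiver, expr_threshold = 0) {
  stopifnot(inherits(db, "lr_database"))
  if (expr_threshold < 0) stop("expr_threshold must be >= 0", call. = FALSE)
  if (any(receiver < 0)) stop("receiver expression must be non-negative", call. = FALSE)
  expr <- function(g) ifelse(g %in% names(receiver), unname(receiver[g]), 0)
  hit <- vapply(seq_len(nrow(db)), function(i) {
    db$ligand[i] %in% ligands &&
      all(expr(db$receptors[[i]]) > expr_threshold)
  }, TRUE)
  out <- db[hit, , drop = FALSE]
  out$min_subunit_expr <- vapply(out$receptors, function(r) min(expr(r)), 0)
  out
}

# scale one gene's expression to [0, 10] across a population panel
minmax_scale <- function(x, lo, hi) {
  if (hi <= lo) return(rep(0, length(x)))
  10 * (x - lo) / (hi - lo)
}

#' Communication scores per ligand-receptor family
#'
#' Per-pair contribution = scaled sender ligand expression times the minimum
#' scaled receiver expression over the receptor subunits (a receptor needs
#' all chains); the family score is the sum of its pairs' contributions. With
#' `scaling = "minmax_0_10"`, every gene is first rescaled to \[0, 10\] across
#' the supplied population panel, so scores are invariant to global rescaling
#' of the expression units. Higher scores mean more, and more strongly
#' expressed, matching pairs in that family.
#'
#' @param sender_expr named numeric vector: ligand expression in the sender
#'   population (e.g. injured mural cells).
#' @param receiver named numeric vector: receptor expression in the receiver
#'   population (a sensory-neuron subtype).
#' @param matched matched pairs from [match_ligand_receptor()].
#' @param scaling `"minmax_0_10"` (default) or `"none"`.
#' @param panel optional gene x population expression matrix over which the
#'   min-max scaling runs; defaults to the two supplied profiles.
#' @param sender_label,receiver_label labels carried into the output.
#' @return data.frame with one row per family present in `matched` (`sender`,
#'   `receiver`, `family`, `score`) and the per-pair contributions in
#'   `attr(, "contributions")`. Zero matched pairs give zero rows.
#' @export
communication_scores <- function(sender_expr, receiver, matched,
                                 scaling = c("minmax_0_10", "none"),
                                 panel = NULL,
                                 sender_label = "sender",
                                 receiver_label = "receiver") {
  scaling <- match.arg(scaling)
  stopifnot(inherits(matched, "lr_database") || is.data.frame(matched))
  genes_needed <- unique(c(matched$ligand, unlist(matched$receptors)))
  for (g in matched$ligand)
    if (!g %in% names(sender_expr))
      stop("matched ligand '", g, "' absent from the sender expression table",
           call. = FALSE)
  for (g in unlist(matched$receptors))
    if (!g %in% names(receiver))
      stop("matched receptor subunit '", g, "' absent from the receiver ",
           "expression table", call. = FALSE)
  if (is.null(panel))
    panel <- expression_panel(sender = sender_expr, receiver = receiver)
  scale_val <- function(x, gene) {
    if (scaling == "none") return(x)
    if (!gene %in% rownames(panel))
      stop("gene '", gene, "' absent from the scaling panel", call. = FALSE)
    rng <- range(panel[gene, ], na.rm = TRUE)
    minmax_scale(x, rng[1], rng[2])
  }
  if (nrow(matched) == 0L) {
    empty <- data.frame(sender = character(), receiver = character(),
                        ligand = character(), receptor = character(),
                        family = character(), contribution = numeric())
    return(structure(data.frame(sender = character(), receiver = character(),
                                family = character(), score = numeric()),
                     contributions = empty))
  }
  contrib <- vapply(seq_len(nrow(matched)), function(i) {
    lg <- matched$ligand[i]
    s <- scale_val(unname(sender_expr[lg]), lg)
    rmin <- min(vapply(matched$receptors[[i]], function(g)
      scale_val(unname(receiver[g]), g), 0))
    s * rmin
  }, 0)
  contributions <- data.frame(
    sender = sender_label, receiver = receiver_label,
    ligand = matched$ligand,
    receptor = vapply(matched$receptors, paste, "", collapse = ";"),
    family = matched$family,
    contribution = if (length(contrib)) contrib else numeric())
  fam_scores <- if (nrow(contributions)) {
    agg <- stats::aggregate(contribution ~ family, contributions, sum)
    data.frame(sender = sender_label, receiver = receiver_label,
               family = agg$family, score = agg$contribution)
  } else data.frame(sender = character(), receiver = character(),
                    family = character(), score = numeric())
  structure(fam_scores, contributions = contributions)
}

#' Compare enabled-interaction counts before and after injury
#'
#' Two-sided Fisher exact test on the 2x2 table (matched vs unmatched pairs,
#' pre vs post injury), with the direction of change reported.
#'
#' @param pre_count,post_count number of enabled ligand-receptor pairs before
#'   and after injury.
#' @param universe_size total number of candidate pairs considered.
#' @return a `test_result` with odds ratio, p-value and `direction`.
#' @export
compare_interaction_counts <- function(pre_count, post_count, universe_size) {
  if (pre_count < 0 || post_count < 0 || pre_count > universe_size ||
      post_count > universe_size)
    stop("counts must lie in [0, universe_size]", call. = FALSE)
  tab <- matrix(c(pre_count, universe_size - pre_count,
                  post_count, universe_size - post_count), nrow = 2L,
                dimnames = list(c("matched", "unmatched"), c("pre", "post")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  direction <- if (post_count > pre_count) "post > pre"
               else if (post_count < pre_count) "post < pre" else "no change"
  structure(list(method = "fisher_exact", statistic = c(odds_ratio = unname(ft$estimate)),
                 p_value = ft$p.value, direction = direction, table = tab),
            class = "test_result")
}

#' Assemble a gene x population expression panel for min-max scaling
#'
#' Combines any number of named expression vectors and gene x population
#' matrices into one matrix over the union of their genes, suitable as the
#' `panel` argument of [communication_scores()]. A gene absent from a
#' population is taken as not expressed there (0), matching the convention of
#' [match_ligand_receptor()]; this keeps the min-max range of a gene
#' non-degenerate whenever any population expresses it.
#'
#' @param ... named numeric vectors and/or matrices with gene rownames.
#' @return numeric matrix, genes in rows, populations in columns.
#' @export
expression_panel <- function(...) {
  parts <- list(...)
  cols <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (is.matrix(p)) {
      for (j in seq_len(ncol(p)))
        cols[[colnames(p)[j] %||% paste0("pop", length(cols) + 1L)]] <- p[, j]
    } else {
      nm <- names(parts)[i]
      if (is.null(nm) || nm == "") nm <- paste0("pop", length(cols) + 1L)
      cols[[nm]] <- p
    }
  }
  genes <- sort(unique(unlist(lapply(cols, names))))
  out <- vapply(cols, function(v) {
    x <- rep(0, length(genes))
    x[match(names(v), genes)] <- unname(v)
    x
  }, numeric(length(genes)))
  rownames(out) <- genes
  out
}

#' Toy injury differential-expression table
#'
#' Emulates a DESeq2 results table for injured versus control nerve stromal
#' cells: a set of known injury-upregulated ligands (Il6, Lif, Clcf1, Ccl2,
#' Ngf, Tnc, Spp1, Mmp9) with large positive log2 fold changes and tiny
#' adjusted p-values, on a background of mostly unregulated genes.
#'
#' @param n_background number of background genes.
#' @param seed integer seed.
#' @param injury_log2fc_range range of log2 fold changes for the injury
#'   ligands (all above the eightfold volcano cutoff by default).
#' @return data.frame with columns `gene`, `log2fc`, `padj`, `mean_injured`,
#'   `mean_control`.
#' @export
simulate_de_table <- function(n_background = 500L, seed = 1L,
                              injury_log2fc_range = c(3.2, 6)) {
  set.seed(seed)
  injury <- c("Il6", "Lif", "Clcf1", "Ccl2", "Ngf", "Tnc", "Spp1", "Mmp9")
  bg <- sprintf("Gene%04d", seq_len(n_background))
  lfc_bg <- stats::rnorm(n_background, 0, 0.8)
  p_bg <- stats::runif(n_background)^0.5  # mostly non-significant
  lfc_inj <- stats::runif(length(injury), injury_log2fc_range[1],
                          injury_log2fc_range[2])
  p_inj <- stats::runif(length(injury), 1e-12, 1e-4)
  base <- stats::rlnorm(n_background + length(injury), meanlog = 4, sdlog = 1)
  lfc <- c(lfc_inj, lfc_bg)
  de <- data.frame(gene = c(injury, bg), log2fc = lfc, padj = c(p_inj, p_bg))
  de$mean_control <- base
  de$mean_injured <- base * 2^lfc
  de
}

#' Built-in ligand-receptor pair database
#'
#' A small curated database of mouse pairs relevant to nerve-injury
#' signalling, with multi-subunit receptors spelled out (the gp130 cytokines
#' Il6, Lif and Clcf1 all require Il6st) and family labels matching the
#' communication-score categories.
#'
#' @return an [lr_database()].
#' @export
default_lr_database <- function() {
  lr_database(
    ligand = c("Il6", "Lif", "Clcf1", "Ccl2", "Ngf", "Ngf",
               "Tnc", "Spp1", "Mmp9", "Ncam1", "Tgfb1", "Cx3cl1",
               "Col1a1", "Bdnf"),
    receptors = c("Il6ra;Il6st", "Lifr;Il6st", "Cntfr;Lifr;Il6st", "Ccr2",
                  "Ntrk1", "Ngfr", "Itga9;Itgb1", "Itgav;Itgb3", "Lrp1",
                  "Ncam1", "Tgfbr1;Tgfbr2", "Cx3cr1", "Itga1;Itgb1",
                  "Ntrk2"),
    family = c("cytokine", "cytokine", "cytokine", "chemokine",
               "growth factor", "growth factor", "ECM", "ECM", "ECM",
               "adhesion", "growth factor", "chemokine", "ECM",
               "growth factor"),
    source = "curated-demo"
  )
}

#' Toy receiver expression profiles for sensory-neuron subtypes
#'
#' Gene x population expression matrix for three receiver populations
#' (neurofilament-positive neurons, nociceptors, cLTMRs), expressing the
#' cognate receptors of the built-in database — including the gp130 subunit
#' Il6st in all three — at population-specific levels.
#'
#' @param seed integer seed for the expression noise.
#' @return numeric matrix, genes in rows, populations `NF`, `nociceptor`,
#'   `cLTMR` in columns.
#' @export
simulate_receiver_profiles <- function(seed = 1L) {
  set.seed(seed)
  genes <- c("Il6ra", "Il6st", "Lifr", "Cntfr", "Ccr2", "Ntrk1", "Ngfr",
             "Itga9", "Itgb1", "Itgav", "Itgb3", "Lrp1", "Ncam1", "Tgfbr1",
             "Tgfbr2", "Cx3cr1", "Itga1", "Ntrk2")
  base <- matrix(stats::rlnorm(length(genes) * 3L, meanlog = 2, sdlog = 0.5),
                 nrow = length(genes),
                 dimnames = list(genes, c("NF", "nociceptor", "cLTMR")))
  # subtype structure: nociceptors rich in Ntrk1/Ngfr/Ccr2, NF in Ntrk2/Ncam1
  base["Ntrk1", "nociceptor"] <- base["Ntrk1", "nociceptor"] * 4
  base["Ngfr", "nociceptor"] <- base["Ngfr", "nociceptor"] * 3
  base["Ccr2", "nociceptor"] <- base["Ccr2", "nociceptor"] * 2
  base["Ntrk2", "NF"] <- base["Ntrk2", "NF"] * 4
  base["Ncam1", "NF"] <- base["Ncam1", "NF"] * 2
  base["Ntrk1", "NF"] <- 0       # NF neurons lack the NGF high-affinity receptor
  base["Ccr2", "cLTMR"] <- 0
  base
}
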