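#' Simulation design for synthetic study inputs
#'
#' Bundles every knob of the synthetic-data generators with defaults sized
#' for a desk-scale study: a 2000-gene background over 50 pathways of 8-20
#' enzymes keeps full-pipeline runs under a minute while leaving the
#' hypergeometric tails well away from degenerate counts. Planted diseases
#' draw 60% of their genes from one target subpathway; class assortativity
#' makes same-class diseases share targets, which is what plants the BD/BH
#' clustering signal. Gene-class membership follows a logistic trend in
#' subpathway degree (positive for disease and tissue-specific genes,
#' negative for essential genes, flat for housekeeping genes), and
#' expression profiles carry per-subpathway coexpression blocks over
#' disease and tissue-specific genes at a target pairwise correlation.
#'
#' @param n_pathways Number of pathways.
#' @param enzymes_per_pathway Integer range `c(min, max)` of enzymes.
#' @param edge_density Edge probability of the random enzyme graphs (a
#'   random spanning tree is always included, so graphs are connected).
#' @param genes_per_enzyme Integer range of genes annotated per enzyme.
#' @param n_background_genes Size of the gene universe.
#' @param n_diseases Number of diseases.
#' @param n_disease_classes Number of disease classes.
#' @param genes_per_disease Integer range of disease gene-set sizes.
#' @param n_planted Number of diseases with a planted target subpathway.
#' @param signal_fraction Fraction of a planted disease's genes drawn from
#'   its target subpathway.
#' @param class_assortativity Probability that a planted disease uses its
#'   class's shared target rather than a random one.
#' @param ratio_trend_strengths Named numeric: logistic slope (per SD of
#'   degree score) of class membership for `disease`, `essential`, `hk`,
#'   `ts`.
#' @param class_base_rates Named numeric: baseline membership probability
#'   of the four classes.
#' @param coexpression_block_r Target within-block pairwise Pearson
#'   correlation.
#' @param n_tissues Number of tissues in the expression panel.
#' @param noise_sd Scale of the expression noise.
#' @param k Distance parameter used when the design is run end to end.
#' @param alpha Enrichment significance cutoff.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_pathways = 50,
                              enzymes_per_pathway = c(8, 20),
                              edge_density = 0.25,
                              genes_per_enzyme = c(1, 3),
                              n_background_genes = 2000,
                              n_diseases = 120,
                              n_disease_classes = 12,
                              genes_per_disease = c(10, 40),
                              n_planted = 60,
                              signal_fraction = 0.6,
                              class_assortativity = 0.8,
                              ratio_trend_strengths = c(disease = 1.5,
                                                        essential = -1.5,
                                                        hk = 0, ts = 1.5),
                              class_base_rates = c(disease = 0.19,
                                                   essential = 0.17,
                                                   hk = 0.1, ts = 0.07),
                              coexpression_block_r = 0.7,
                              n_tissues = 36,
                              noise_sd = 1,
                              k = 3,
                              alpha = 0.01) {
  d <- list(n_pathways = n_pathways,
            enzymes_per_pathway = enzymes_per_pathway,
            edge_density = edge_density,
            genes_per_enzyme = genes_per_enzyme,
            n_background_genes = n_background_genes,
            n_diseases = n_diseases,
            n_disease_classes = n_disease_classes,
            genes_per_disease = genes_per_disease,
            n_planted = n_planted,
            signal_fraction = signal_fraction,
            class_assortativity = class_assortativity,
            ratio_trend_strengths = ratio_trend_strengths,
            class_base_rates = class_base_rates,
            coexpression_block_r = coexpression_block_r,
            n_tissues = n_tissues,
            noise_sd = noise_sd,
            k = k, alpha = alpha)
  stopifnot(d$edge_density >= 0, d$edge_density <= 1,
            d$signal_fraction >= 0, d$signal_fraction <= 1,
            d$class_assortativity >= 0, d$class_assortativity <= 1,
            d$coexpression_block_r >= 0, d$coexpression_block_r <= 1,
            d$n_planted <= d$n_diseases,
            d$enzymes_per_pathway[1] >= 2,
            d$enzymes_per_pathway[1] <= d$enzymes_per_pathway[2])
  structure(d, class = "simulation_design")
}

metabolism_classes <- c(
  "carbohydrate metabolism", "energy metabolism", "lipid metabolism",
  "nucleotide metabolism", "amino acid metabolism",
  "metabolism of other amino acids", "glycan biosynthesis and metabolism",
  "metabolism of cofactors and vitamins",
  "metabolism of terpenoids and polyketides",
  "biosynthesis of other secondary metabolites",
  "xenobiotics biodegradation and metabolism")

sample_range <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(seq(rng[1], rng[2]), n,
                                                   replace = TRUE)
}

# connected Erdos-Renyi-like graph: random spanning tree + density edges
random_connected_edges <- function(n, density) {
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    parent <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
    edges <- cbind(parent, 2:n)
    extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(extra)) < density
    edges <- unique(rbind(edges, extra[keep, , drop = FALSE]))
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
  }
  edges
}

#' Simulate a pathway collection with gene annotations
#'
#' Generates connected random enzyme graphs and realizes each as a KGML-style
#' reaction list: every enzyme gets one irreversible reaction with a private
#' input and output compound, and every graph edge becomes one shared
#' compound (a product of one enzyme's reaction and a substrate of the
#' other's), so parsing the written KGML and rebuilding the graph
#' reproduces the simulated topology exactly. Each enzyme is annotated
#' with genes drawn from a common background pool.
#'
#' @param design A `simulation_design`.
#' @param seed Integer seed.
#' @return List with `pathways` (list of `pathway_definition`), `annotations`
#'   (a `gene_annotation_map`) and `background` (the full gene pool).
#' @export
simulate_pathways <- function(design, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  pool <- sprintf("g%04d", seq_len(design$n_background_genes))
  pathways <- vector("list", design$n_pathways)
  ann_genes <- character(0); ann_ecs <- character(0)
  for (i in seq_len(design$n_pathways)) {
    n_e <- sample_range(design$enzymes_per_pathway)
    ecs <- sprintf("%d.%d.%d.%d", (i - 1) %/% 100 + 1, (i - 1) %% 100 + 1,
                   1, seq_len(n_e))
    em <- random_connected_edges(n_e, design$edge_density)
    pid <- sprintf("path:s%04d", i)
    reactions <- lapply(seq_len(n_e), function(j) {
      list(reaction_id = sprintf("rn:%s_R%03d", sub("^path:", "", pid), j),
           substrates = sprintf("C%s_in%03d", sub("^path:s", "", pid), j),
           products = sprintf("C%s_out%03d", sub("^path:s", "", pid), j),
           enzymes = ecs[j], reversible = FALSE)
    })
    if (nrow(em) > 0) {
      for (r in seq_len(nrow(em))) {
        a <- em[r, 1]; b <- em[r, 2]
        cpd <- sprintf("C%s_e%03d", sub("^path:s", "", pid), r)
        reactions[[a]]$products <- c(reactions[[a]]$products, cpd)
        reactions[[b]]$substrates <- c(reactions[[b]]$substrates, cpd)
      }
    }
    pathways[[i]] <- new_pathway_definition(
      pid, sprintf("synthetic pathway %d", i),
      metabolism_classes[(i - 1) %% length(metabolism_classes) + 1],
      reactions, sort(ecs))
    for (j in seq_len(n_e)) {
      g <- sample(pool, sample_range(design$genes_per_enzyme))
      ann_genes <- c(ann_genes, g)
      ann_ecs <- c(ann_ecs, rep(ecs[j], length(g)))
    }
  }
  list(pathways = pathways,
       annotations = annotation_map_from_pairs(ann_genes, ann_ecs),
       background = pool)
}

#' Simulate disease gene sets with planted subpathway enrichment
#'
#' The first `n_planted` diseases each receive a target subpathway and draw
#' `signal_fraction` of their genes from its gene set (the rest uniformly
#' from the background); the remaining diseases are pure nulls drawing all
#' genes uniformly. Diseases are spread round-robin over the disease
#' classes, and each class shares one class-level target: a planted disease
#' adopts it with probability `class_assortativity`, otherwise it gets an
#' independent random target. Targets are restricted to subpathways with at
#' least 8 genes so the planted fraction is realizable.
#'
#' @param design A `simulation_design`.
#' @param subpathways Subpathway table from [mine_collection()].
#' @param background Gene universe to draw noise genes from.
#' @param seed Integer seed.
#' @return List with `diseases` (disease gene-set table) and `truth`
#'   (data frame `disease_id`, `subpathway_id` of planted associations).
#' @export
simulate_diseases <- function(design, subpathways, background, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  eligible <- which(subpathways$n_genes >= 8)
  if (design$n_planted > 0 && length(eligible) == 0) {
    stop("no subpathway large enough to host a planted signal")
  }
  n_cls <- design$n_disease_classes
  cls <- sprintf("class%02d", (seq_len(design$n_diseases) - 1) %% n_cls + 1)
  class_target <- stats::setNames(
    sample(eligible, n_cls, replace = length(eligible) < n_cls),
    sprintf("class%02d", seq_len(n_cls)))
  ids <- sprintf("disease%03d", seq_len(design$n_diseases))
  sizes <- sample_range(design$genes_per_disease, design$n_diseases)
  genes <- vector("list", design$n_diseases)
  truth <- data.frame(disease_id = character(0), subpathway_id = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(design$n_diseases)) {
    if (i <= design$n_planted) {
      tgt <- if (stats::runif(1) < design$class_assortativity) {
        class_target[[cls[i]]]
      } else sample(eligible, 1)
      tgt_genes <- subpathways$genes[[tgt]]
      n_sig <- min(round(design$signal_fraction * sizes[i]), length(tgt_genes))
      sig <- sample(tgt_genes, n_sig)
      noise <- sample(setdiff(background, sig), sizes[i] - n_sig)
      genes[[i]] <- sort(c(sig, noise))
      truth <- rbind(truth, data.frame(
        disease_id = ids[i], subpathway_id = subpathways$subpathway_id[tgt],
        stringsAsFactors = FALSE))
    } else {
      genes[[i]] <- sort(sample(background, sizes[i]))
    }
  }
  list(diseases = disease_gene_sets(ids, cls, genes), truth = truth)
}

#' Simulate gene class labels with planted degree trends
#'
#' Assigns each background gene to the disease / essential / HK / TS label
#' sets with a membership probability that is logistic in the gene's
#' subpathway-degree score (the maximum network degree over subpathways
#' containing the gene, standardized): baseline rate plus the per-class
#' trend strength per SD of the score. Positive strengths make the class
#' accumulate in high-degree subpathways, negative ones deplete it; zero
#' leaves the class flat. HK and TS are kept disjoint (TS is drawn among
#' non-HK genes only).
#'
#' @param design A `simulation_design`.
#' @param subpathways Subpathway table.
#' @param net_degrees Named vector of subpathway degrees
#'   ([network_degrees()]).
#' @param background Gene universe to label.
#' @param seed Integer seed.
#' @return A `gene_class_labels` object.
#' @export
simulate_gene_labels <- function(design, subpathways, net_degrees,
                                 background, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  score <- stats::setNames(rep(0, length(background)), background)
  for (sid in names(net_degrees)) {
    j <- match(sid, subpathways$subpathway_id)
    if (is.na(j)) next
    gs <- intersect(subpathways$genes[[j]], background)
    score[gs] <- pmax(score[gs], net_degrees[[sid]])
  }
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else score * 0
  s <- design$ratio_trend_strengths
  b <- design$class_base_rates
  memb <- function(class) {
    p <- stats::plogis(stats::qlogis(b[[class]]) + s[[class]] * z)
    background[stats::runif(length(background)) < p]
  }
  dg <- memb("disease"); eg <- memb("essential")
  hk <- memb("hk")
  ts <- setdiff(memb("ts"), hk)
  gene_class_labels(dg, eg, hk, ts)
}

#' Simulate a tissue expression matrix with coexpression blocks
#'
#' Every gene gets an independent standard-normal profile over the tissues
#' except genes belonging to a planted block, whose profiles mix a shared
#' latent tissue factor at weight `sqrt(r)` with private noise at
#' `sqrt(1-r)`, giving expected pairwise Pearson correlation `r` within the
#' block. One block is planted per network subpathway over its disease and
#' tissue-specific member genes; housekeeping genes never join a block
#' (their expression is constitutive, not subpathway-specific), and a gene
#' in several subpathways joins the first block only, so blocks are
#' disjoint.
#'
#' @param design A `simulation_design`.
#' @param labels A `gene_class_labels` object.
#' @param subpathways Subpathway table.
#' @param net A `subpathway_network` naming the subpathways to plant on
#'   (or `NULL` to plant on every subpathway).
#' @param background Gene universe (matrix rows).
#' @param seed Integer seed.
#' @return Numeric matrix (genes x tissues) with a `blocks` attribute:
#'   named integer vector giving each blocked gene's block index.
#' @export
simulate_expression <- function(design, labels, subpathways, net = NULL,
                                background, seed = 1) {
  stopifnot(inherits(design, "simulation_design"), design$n_tissues >= 3)
  set.seed(seed)
  r <- design$coexpression_block_r
  s_ids <- if (is.null(net)) subpathways$subpathway_id
           else names(net$subpathway_class)
  block_of <- integer(0)
  blocked <- character(0)
  bi <- 0
  for (sid in s_ids) {
    j <- match(sid, subpathways$subpathway_id)
    if (is.na(j)) next
    gs <- subpathways$genes[[j]]
    members <- setdiff(intersect(gs, c(labels$disease_genes,
                                       labels$tissue_specific_genes)),
                       c(blocked, labels$housekeeping_genes))
    if (length(members) >= 2) {
      bi <- bi + 1
      block_of[members] <- bi
      blocked <- c(blocked, members)
    }
  }
  nt <- design$n_tissues
  expr <- matrix(stats::rnorm(length(background) * nt), length(background), nt,
                 dimnames = list(background, sprintf("tissue%02d", 1:nt)))
  if (bi > 0 && r > 0) {
    factors <- matrix(stats::rnorm(bi * nt), bi, nt)
    for (g in names(block_of)) {
      expr[g, ] <- sqrt(r) * factors[block_of[[g]], ] +
        sqrt(1 - r) * expr[g, ]
    }
  }
  expr <- expr * design$noise_sd
  attr(expr, "blocks") <- block_of
  expr
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: simulates the pathway collection, mines subpathways
#' at the design's `k`, and simulates disease gene sets with their ground
#' truth. (Gene labels and expression depend on the assembled network's
#' degrees, so they are simulated afterwards by the caller or by
#' [run_pipeline()].) Sub-seeds are derived deterministically from `seed`.
#'
#' @param design A `simulation_design`.
#' @param seed Integer seed.
#' @return List: `pathways`, `annotations`, `background`, `subpathways`,
#'   `diseases`, `truth`.
#' @export
synthetic_study <- function(design = simulation_design(), seed = 1) {
  pw <- simulate_pathways(design, seed = seed)
  spw <- mine_collection(pw$pathways, k = design$k, ann = pw$annotations)
  dz <- simulate_diseases(design, spw, pw$background, seed = seed + 1e6)
  list(pathways = pw$pathways, annotations = pw$annotations,
       background = pw$background, subpathways = spw,
       diseases = dz$diseases, truth = dz$truth)
}

#' Write a pathway definition as KGML
#'
#' Emits the subset of KGML the package's own parser consumes (enzyme
#' entries referencing reactions; reaction elements with substrate/product
#' children and a reversibility type), so simulated pathways round-trip
#' through [parse_kgml()].
#'
#' @param pw A `pathway_definition`.
#' @param path Output file path.
#' @export
write_kgml <- function(pw, path) {
  stopifnot(inherits(pw, "pathway_definition"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    "<?xml version=\"1.0\"?>",
    sprintf("<pathway name=\"%s\" title=\"%s\">", esc(pw$pathway_id),
            esc(pw$name)))
  eid <- 0
  rx_of_ec <- list()
  for (r in pw$reactions) {
    for (ec in r$enzymes) {
      rx_of_ec[[ec]] <- c(rx_of_ec[[ec]], r$reaction_id)
    }
  }
  for (ec in pw$enzymes) {
    eid <- eid + 1
    rx <- unique(rx_of_ec[[ec]])
    lines <- c(lines, sprintf(
      "  <entry id=\"%d\" name=\"ec:%s\" type=\"enzyme\"%s/>",
      eid, esc(ec),
      if (length(rx)) sprintf(" reaction=\"%s\"", paste(rx, collapse = " "))
      else ""))
  }
  for (r in pw$reactions) {
    eid <- eid + 1
    lines <- c(lines, sprintf(
      "  <reaction id=\"%d\" name=\"%s\" type=\"%s\">",
      eid, esc(r$reaction_id),
      if (isTRUE(r$reversible)) "reversible" else "irreversible"))
    for (s in r$substrates) {
      lines <- c(lines, sprintf("    <substrate id=\"0\" name=\"cpd:%s\"/>", esc(s)))
    }
    for (p in r$products) {
      lines <- c(lines, sprintf("    <product id=\"0\" name=\"cpd:%s\"/>", esc(p)))
    }
    lines <- c(lines, "  </reaction>")
  }
  lines <- c(lines, "</pathway>")
  writeLines(lines, path)
  invisible(path)
}

#' Write every synthetic input in its on-disk exchange format
#'
#' KGML per pathway, gene-EC annotation TSV, GAD-style disease table,
#' and a ground-truth JSON, under `dir`.
#'
#' @param study Result of [synthetic_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(file.path(dir, "kgml"), recursive = TRUE, showWarnings = FALSE)
  classes <- character(0)
  for (pw in study$pathways) {
    write_kgml(pw, file.path(dir, "kgml", paste0(sub("^path:", "", pw$pathway_id), ".xml")))
    classes[pw$pathway_id] <- pw$class_label
  }
  utils::write.table(
    data.frame(pathway_id = names(classes), class_label = unname(classes)),
    file.path(dir, "pathway_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- study$annotations
  pairs <- data.frame(
    gene_id = rep(names(ann$gene2ec), lengths(ann$gene2ec)),
    ec = unlist(ann$gene2ec, use.names = FALSE))
  utils::write.table(pairs, file.path(dir, "gene_ec.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gad_table(study$diseases, file.path(dir, "disease_gene.tsv"))
  writeLines(study$background, file.path(dir, "background_genes.txt"))
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
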