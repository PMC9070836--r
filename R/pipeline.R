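#' Pipeline configuration
#'
#' One declarative configuration for the whole pipeline: stage toggles
#' and every stage parameter, with the study's printed defaults (blur
#' sigma 2.0; FDR 0.1; log2FC 1; t-SNE perplexity 20, early-exaggeration
#' "lying" phase 250, cluster-size cutoff 20, seed 2; network quantile
#' cutoff 0.997; 5-kb promoter window; W-box motif TTGACY; extinction
#' coefficient 17.2). Configurations round-trip through YAML unchanged
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param stages named logical list toggling pipeline stages.
#' @param imaging,dge,embed,network,variants,chem per-stage parameter
#'   lists; supplied entries override the defaults.
#' @param inputs named list of input paths for non-synthetic runs
#'   (`counts_prefix` for a [write_count_matrix()] pair; `vcf`, `gff3`,
#'   `fasta` for the variant stage).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 2L,
                            stages = list(),
                            imaging = list(),
                            dge = list(),
                            embed = list(),
                            network = list(),
                            variants = list(),
                            chem = list(),
                            inputs = list()) {
  cfg <- list(
    seed = as.integer(seed),
    stages = modifyList(list(imaging = TRUE, dge = TRUE, embed = TRUE,
                             network = TRUE, variants = TRUE, chem = TRUE),
                        stages),
    imaging = modifyList(list(sigma = 2.0,
                              fractions = c(0.02, 0.05, 0.03, 0.45),
                              labels = c("susceptible-Cc", "susceptible+Cc",
                                         "resistant-Cc", "resistant+Cc")),
                         imaging),
    dge = modifyList(list(fdr = 0.1, log2fc = 1, fc = 1.5,
                          n_genes = 2000L, n_rep = 5L,
                          genotype_test = "H9553", genotype_ref = "H9775"),
                     dge),
    embed = modifyList(list(perplexity = 20, lying = 250, cutoff = 20,
                            seed = 2L, n_iter = 1000L, max_genes = 400L),
                       embed),
    network = modifyList(list(q = 0.997, mode = "normal", max_genes = 300L),
                         network),
    variants = modifyList(list(window = 5000L, motif = "TTGACY",
                               resistant = c("H9553", "H9492"),
                               susceptible = "H9775"),
                          variants),
    chem = modifyList(list(extinction = 17.2, path_cm = 1.0), chem),
    inputs = inputs
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(seed = x$seed, stages = x$stages, imaging = x$imaging,
                  dge = x$dge, embed = x$embed, network = x$network,
                  variants = x$variants, chem = x$chem,
                  inputs = if (is.null(x$inputs)) list() else x$inputs)
}

#' @noRd
manifest_add <- function(manifest, stage, files) {
  files <- unname(unlist(files))
  manifest$stages[[stage]] <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  manifest
}

#' @noRd
default_synthetic_plans <- function(n_strata) {
  ## stratum order (default design): H1706 un/inf, H9775 un/inf,
  ## H9492 un/inf, H9553 un/inf
  stopifnot(n_strata == 8L)
  up_inf_resistant <- c(0, 0, 0, 0, 0, 4, 0, 4)
  up_inf_all <- c(0, 3, 0, 3, 0, 3, 0, 3)
  down_inf_susceptible <- c(0, -3, 0, -3, 0, 0, 0, 0)
  list(
    cluster_plan = list(
      list(size = 60, shift = up_inf_resistant),
      list(size = 60, shift = up_inf_all),
      list(size = 60, shift = down_inf_susceptible)
    ),
    module_plan = list(
      ## a defence module active only in infested resistant cultivars,
      ## with a hub gene (the CuRe1/SlWRKY16-like behaviour)
      list(size = 40, cor = 0.9, hub = TRUE, strata = c(6, 8),
           shift = up_inf_resistant),
      ## a housekeeping-like module co-expressed everywhere
      list(size = 40, cor = 0.8, hub = FALSE, shift = up_inf_all)
    )
  )
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (differential
#' expression, then embedding/clustering, then networks; imaging,
#' variants and chemistry are independent), writes every stage output
#' under `out_dir`, and records each written file with its MD5 content
#' hash in a JSON manifest. A rerun with the same configuration and
#' seeds reproduces the hashes.
#'
#' In synthetic mode every input is generated by the package's
#' generators with ground truth planted according to the configuration;
#' otherwise the paths in `config$inputs` are read (and must all exist
#' before any stage runs).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param synthetic generate inputs with the synthetic-data module?
#' @param quiet suppress progress messages?
#' @return The manifest (list), invisibly. Side effects: files under
#'   `out_dir`, including `manifest.json` and `report.txt`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "dodderlign-run",
                         synthetic = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!synthetic) {
    need <- unlist(config$inputs)
    if (!length(need)) stopf("non-synthetic mode needs input paths in config$inputs")
    missing <- need[!file.exists(need)]
    if (length(missing)) {
      stopf("missing input file(s): %s", paste(missing, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(out_dir = out_dir, seed = config$seed, stages = list())
  base_seed <- config$seed

  ## ---- imaging ----------------------------------------------------------
  if (isTRUE(config$stages$imaging)) {
    say("imaging: quantifying %d sections", length(config$imaging$fractions))
    params <- imaging_params(sigma = config$imaging$sigma)
    rows <- list(); files <- character(0)
    for (i in seq_along(config$imaging$fractions)) {
      label <- config$imaging$labels[i]
      if (synthetic) {
        img <- render_section(section_spec(
          cortex_stain_fraction = config$imaging$fractions[i],
          seed = base_seed * 100L + i
        ))
        truth <- 100 * sum(img$masks$stained_cortex) / sum(img$masks$cortex)
      } else {
        img <- read_section_png(config$inputs$images[i])
        truth <- NA_real_
      }
      q <- quantify_section(img, params = params)
      ov <- file.path(out_dir, sprintf("section_%s_overlay.png", label))
      write_overlay_png(img, attr(q, "mask"), ov)
      files <- c(files, ov)
      rows[[i]] <- data.frame(
        section = label,
        total_lignin_px = q$total_lignin_px,
        xylem_lignin_px = q$xylem_lignin_px,
        cortex_lignin_px = q$cortex_lignin_px,
        cortex_area_px = q$cortex_area_px,
        cortex_lignin_pct = q$cortex_lignin_pct,
        truth_pct = truth
      )
    }
    lf <- file.path(out_dir, "lignin_quant.tsv")
    write.table(do.call(rbind, rows), lf, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- manifest_add(manifest, "imaging", c(lf, files))
  }

  ## ---- differential expression ------------------------------------------
  cm <- NULL; deg_anova <- NULL
  if (isTRUE(config$stages$dge) || isTRUE(config$stages$embed) ||
      isTRUE(config$stages$network)) {
    if (synthetic) {
      plans <- default_synthetic_plans(8L)
      cm <- simulate_counts(expr_sim_spec(
        n_genes = config$dge$n_genes,
        strata = default_strata(config$dge$n_rep),
        cluster_plan = plans$cluster_plan,
        module_plan = plans$module_plan,
        seed = base_seed * 100L + 11L
      ))
    } else {
      cm <- read_count_matrix(config$inputs$counts_prefix)
    }
  }
  if (isTRUE(config$stages$dge)) {
    say("dge: interaction model and two-factor ANOVA on %d genes", nrow(cm$counts))
    thr <- dge_thresholds(fdr_max = config$dge$fdr,
                          log2fc_min = config$dge$log2fc,
                          fc_min = config$dge$fc)
    deg_int <- interaction_dge(cm, config$dge$genotype_test,
                               config$dge$genotype_ref, thr)
    deg_anova <- twofactor_anova_dge(cm, thr)
    f1 <- file.path(out_dir, "dge_interaction.tsv")
    f2 <- file.path(out_dir, "dge_anova.tsv")
    write_dge_result(deg_int, f1)
    write_dge_result(deg_anova, f2)
    cfiles <- write_count_matrix(cm, file.path(out_dir, "expression"))
    manifest <- manifest_add(manifest, "dge", c(f1, f2, cfiles))
  }

  ## ---- embedding + clustering -------------------------------------------
  assignment <- NULL; emb_genes <- NULL
  if (isTRUE(config$stages$embed)) {
    if (is.null(deg_anova)) deg_anova <- twofactor_anova_dge(cm)
    sel <- deg_anova$gene[deg_anova$passes]
    sel <- sel[order(deg_anova$p[match(sel, deg_anova$gene)])]
    if (length(sel) > config$embed$max_genes) sel <- sel[seq_len(config$embed$max_genes)]
    say("embed: t-SNE on %d DEGs", length(sel))
    z <- zscore_rows(log2cpm(cm)[sel, , drop = FALSE])
    coords <- tsne_embed(z, tsne_params(
      perplexity = config$embed$perplexity, lying = config$embed$lying,
      seed = config$embed$seed, n_iter = config$embed$n_iter
    ))
    assignment <- density_cluster(coords, cutoff = config$embed$cutoff)
    emb_genes <- sel
    ef <- file.path(out_dir, "embedding.tsv")
    write_embedding(coords, assignment, ef)
    pf <- file.path(out_dir, "cluster_profiles.tsv")
    write.table(cluster_summary(assignment, z), pf, sep = "\t",
                quote = FALSE, col.names = NA)
    manifest <- manifest_add(manifest, "embed", c(ef, pf))
  }

  ## ---- co-expression networks -------------------------------------------
  if (isTRUE(config$stages$network)) {
    if (!is.null(assignment)) {
      gene_list <- emb_genes[assignment$labels > 0]
    } else {
      if (is.null(deg_anova)) deg_anova <- twofactor_anova_dge(cm)
      gene_list <- deg_anova$gene[deg_anova$passes]
    }
    if (length(gene_list) > config$network$max_genes) {
      gene_list <- gene_list[seq_len(config$network$max_genes)]
    }
    say("network: stratified GCNs over %d genes (q = %g)",
        length(gene_list), config$network$q)
    gcns <- build_stratified_gcns(cm, gene_list, q = config$network$q,
                                  mode = config$network$mode)
    files <- character(0)
    hub_rows <- list()
    for (label in names(gcns)) {
      files <- c(files, write_gcn(gcns[[label]]$graph,
                                  file.path(out_dir, paste0("gcn_", label))))
      hb <- gcns[[label]]$hubs
      hub_rows[[label]] <- data.frame(
        stratum = label, gene = names(hb$degrees),
        degree = unname(hb$degrees),
        module = unname(gcns[[label]]$modules$membership[names(hb$degrees)]),
        isolated = names(hb$degrees) %in% hb$isolated
      )
    }
    hf <- file.path(out_dir, "gcn_hubs.tsv")
    hub_tab <- do.call(rbind, hub_rows)
    hub_tab <- hub_tab[order(hub_tab$stratum, -hub_tab$degree, hub_tab$gene), ]
    write.table(hub_tab, hf, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- manifest_add(manifest, "network", c(hf, files))
  }

  ## ---- variants + motifs -------------------------------------------------
  if (isTRUE(config$stages$variants)) {
    say("variants: resistance-specific SNP and W-box analysis")
    if (synthetic) {
      sim <- simulate_variants(variant_sim_spec(seed = base_seed * 100L + 21L))
      variants <- sim$variants; genes <- sim$genes; reference <- sim$reference
    } else {
      variants <- read_variant_vcf(config$inputs$vcf)
      reference <- {
        ss <- Biostrings::readDNAStringSet(config$inputs$fasta)
        setNames(as.character(ss), names(ss))
      }
      genes <- read.table(config$inputs$genes, sep = "\t", header = TRUE)
    }
    rs <- resistance_specific_snps(variants,
                                   resistant = config$variants$resistant,
                                   susceptible = config$variants$susceptible)
    clens <- setNames(nchar(reference), names(reference))
    prom <- promoter_windows(genes, window = config$variants$window,
                             chrom_lengths = clens)
    hits <- scan_motif(reference[1], pattern = config$variants$motif,
                       both_strands = TRUE, chrom = names(reference)[1])
    overlap <- snp_motif_overlap(rs, hits, prom,
                                 pattern = config$variants$motif)
    vf <- file.path(out_dir, "variants.vcf")
    rf <- file.path(out_dir, "resistance_specific.vcf")
    ff <- file.path(out_dir, "reference.fasta")
    gf <- file.path(out_dir, "genes.gff3")
    bf <- file.path(out_dir, "promoters.bed")
    mf <- file.path(out_dir, "wbox_hits.tsv")
    of <- file.path(out_dir, "snp_motif_overlap.tsv")
    write_variant_vcf(variants, vf, contig_length = unname(clens[1]))
    write_variant_vcf(rs, rf, contig_length = unname(clens[1]))
    write_reference_fasta(reference, ff)
    write_genes_gff3(genes, gf)
    write_promoter_bed(prom, bf)
    write.table(hits, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(overlap, of, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- manifest_add(manifest, "variants",
                             c(vf, rf, ff, gf, bf, mf, of))
  }

  ## ---- lignin chemistry ---------------------------------------------------
  if (isTRUE(config$stages$chem)) {
    say("chem: %%ABSL and pyrogram composition")
    if (synthetic) {
      groups <- c("GUS", "SlMYB55", "LIF1", "CuRLR1-Cc", "CuRLR1+Cc")
      mean_abs <- c(8, 13, 13.5, 12, 17) * 0.172  # ~8-17 %ABSL at 100 mg/mL
      absd <- with_seed(base_seed * 100L + 31L, data.frame(
        group = rep(groups, each = 4),
        absorbance = pmax(0.05, rep(mean_abs, each = 4) +
                            rnorm(20, sd = 0.08)),
        biomass_mg = 100, volume_mL = 10
      ))
      pyro <- with_seed(base_seed * 100L + 32L, data.frame(
        compound = c("phenol", "4-vinylphenol", "guaiacol", "4-vinylguaiacol",
                     "isoeugenol", "syringol", "4-methylsyringol",
                     "syringaldehyde", "4-vinylphenol (coumarate)", "toluene"),
        class = c("H", "H", "G", "G", "G", "S", "S", "S", "p-coumarate",
                  "other"),
        area = round(runif(10, 1e4, 2e5))
      ))
    } else {
      absd <- read.table(config$inputs$absorbance, sep = "\t", header = TRUE)
      pyro <- read.table(config$inputs$pyrogram, sep = "\t", header = TRUE)
    }
    absd$absl_pct <- absl_percent(absd$absorbance, absd$biomass_mg,
                                  absd$volume_mL,
                                  path_cm = config$chem$path_cm,
                                  extinction = config$chem$extinction)
    np <- normalize_pyrogram(pyro)
    af <- file.path(out_dir, "absl.tsv")
    cf <- file.path(out_dir, "pyrogram_compounds.tsv")
    kf <- file.path(out_dir, "pyrogram_classes.tsv")
    write.table(absd, af, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(np$compounds, cf, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(np$classes, kf, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- manifest_add(manifest, "chem", c(af, cf, kf))
  }

  mj <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA)
  write_report(manifest, file.path(out_dir, "report.txt"))
  say("done: %s", out_dir)
  invisible(manifest)
}

#' Write a human-readable run report
#'
#' Summarises a pipeline run from its manifest and the files the
#' manifest lists: per-section cortex lignin percentages, DEG counts,
#' the cluster table, per-stratum top hubs and the SNP/W-box overlap
#' table. Only files recorded in the manifest are read.
#'
#' @param manifest a [run_pipeline()] manifest (or path to
#'   `manifest.json`).
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(manifest, path) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  out_dir <- manifest$out_dir
  lines <- c("dodderlign pipeline report", "==========================", "")
  has <- function(stage, file) {
    !is.null(manifest$stages[[stage]]) &&
      file %in% manifest$stages[[stage]]$file &&
      file.exists(file.path(out_dir, file))
  }
  rd <- function(file) read.table(file.path(out_dir, file), sep = "\t",
                                  header = TRUE, check.names = FALSE)
  if (has("imaging", "lignin_quant.tsv")) {
    lq <- rd("lignin_quant.tsv")
    lines <- c(lines, "Cortex lignin per section:",
               sprintf("  %-16s %6.2f %%%s", lq$section, lq$cortex_lignin_pct,
                       ifelse(is.na(lq$truth_pct), "",
                              sprintf(" (truth %.2f %%)", lq$truth_pct))),
               "")
  }
  if (has("dge", "dge_interaction.tsv")) {
    di <- rd("dge_interaction.tsv"); da <- rd("dge_anova.tsv")
    lines <- c(lines,
               sprintf("Interaction DEGs (FDR < 0.1, |log2FC| > 1): %d of %d genes",
                       sum(di$passes), nrow(di)),
               sprintf("Two-factor ANOVA DEGs (FDR < 0.1): %d of %d genes",
                       sum(da$passes), nrow(da)), "")
  }
  if (has("embed", "embedding.tsv")) {
    em <- rd("embedding.tsv")
    sizes <- table(em$cluster[em$cluster > 0])
    lines <- c(lines,
               sprintf("Expression clusters: %d clusters (%d genes), %d in the noise group",
                       length(sizes), sum(sizes), sum(em$cluster == 0)),
               if (length(sizes)) {
                 sprintf("  cluster %s: %d genes", names(sizes), as.integer(sizes))
               }, "")
  }
  if (has("network", "gcn_hubs.tsv")) {
    hb <- rd("gcn_hubs.tsv")
    lines <- c(lines, "Top hub per stratum (by degree):")
    for (s in unique(hb$stratum)) {
      hs <- hb[hb$stratum == s, ]
      hs <- hs[order(-hs$degree, hs$gene), ]
      lines <- c(lines, sprintf("  %-22s %s (degree %d; %d isolated genes)",
                                s, hs$gene[1], hs$degree[1], sum(hs$isolated)))
    }
    lines <- c(lines, "")
  }
  if (has("variants", "snp_motif_overlap.tsv")) {
    ov <- rd("snp_motif_overlap.tsv")
    rs <- readLines(file.path(out_dir, "resistance_specific.vcf"))
    nrs <- sum(!startsWith(rs, "#"))
    lines <- c(lines, sprintf("Resistance-specific SNPs: %d", nrs),
               sprintf("SNPs inside promoter W-box motifs: %d (motif-breaking: %d)",
                       nrow(ov), sum(ov$breaks_motif)), "")
  }
  if (has("chem", "absl.tsv")) {
    ab <- rd("absl.tsv")
    agg <- aggregate(absl_pct ~ group, data = ab, FUN = mean)
    cls <- rd("pyrogram_classes.tsv")
    lines <- c(lines, "Mean %ABSL per group:",
               sprintf("  %-12s %5.2f %%", agg$group, agg$absl_pct),
               "Pyrogram class fractions:",
               sprintf("  %-12s %5.3f", cls$class, cls$fraction), "")
  }
  writeLines(lines, path)
  invisible(path)
}
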