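#' Read and write the pipeline's tabular formats
#'
#' Tables travel as plain TSV. Genotype matrices are written subjects x SNPs
#' with "." for missing calls, and can optionally be exported as a minimal
#' unphased VCF (GT field only).
#'
#' @param x data.frame or genotype matrix.
#' @param path file path.
#' @name onecarbon_io
NULL

#' @rdname onecarbon_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname onecarbon_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname onecarbon_io
#' @export
write_genotypes_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) ifelse(is.na(col), ".", as.character(col)))
  df <- cbind(subject_id = rownames(x), df)
  write_tsv(df, path)
}

#' @rdname onecarbon_io
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv(path)
  ids <- df$subject_id
  df$subject_id <- NULL
  m <- as.matrix(df)
  m[m == "."] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname onecarbon_io
#' @export
write_genotypes_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(x)), collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(x))) {
    g <- x[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    writeLines(paste(c("1", j, colnames(x)[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Default pipeline configuration
#'
#' One root seed drives named substreams per stage. FDR thresholds follow
#' the analysis convention: 0.05 for metabolomic, 0.10 for genomic effects.
#'
#' @param seed root seed.
#' @param out output directory.
#' @param gp_scaled_down use the reduced GP budget.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out = tempfile("ocrun"),
                               gp_scaled_down = TRUE) {
  structure(list(
    seed = as.integer(seed), out = out,
    cohort = list(levodopa_fraction = 0.5),
    effects = list(
      list(metabolite = "biotin", group = "AD-D", effect = -0.73),
      list(metabolite = "THF", group = "AD-D", effect = -0.53),
      list(metabolite = "PLP", group = "AD-D", effect = -0.51),
      list(metabolite = "biotin", group = "PD-D", effect = -0.6),
      list(metabolite = "PLP", group = "PD-D", effect = -0.5),
      list(metabolite = "Hcy", group = "PD-D", effect = 1.0,
           levodopa_only = TRUE)
    ),
    snps = list(
      list(snp_id = "rs_r1", maf = 0.3, effect_hcy = 0.5),
      list(snp_id = "rs_p1", maf = 0.3, effect_hcy = -0.5),
      list(snp_id = "rs_n1", maf = 0.2), list(snp_id = "rs_n2", maf = 0.25),
      list(snp_id = "rs_n3", maf = 0.35), list(snp_id = "rs_n4", maf = 0.15)
    ),
    fdr = list(metabolomic = 0.05, genomic = 0.10),
    merge_groups = list(Dementia = c("AD-D", "PD-D")),
    gp = list(scaled_down = gp_scaled_down,
              target = c("PD-D", "PD-ND"))
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with the same structure as [default_run_config()];
#' missing fields fall back to the defaults.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]) &&
                    !is.null(names(user[[k]])))
      utils::modifyList(cfg[[k]], user[[k]])
    else user[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> preprocess -> differential -> SNP association -> composite
#' scores -> GP classification, writing each stage's tables under the output
#' directory with a JSON manifest (config hash, seeds, stage file list).
#' Reruns with the same config reproduce identical outputs.
#'
#' @param config a [default_run_config()] list.
#' @return the output directory path (with attribute `manifest`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  seed <- config$seed

  # simulate
  cc <- cohort_config(levodopa_fraction = config$cohort$levodopa_fraction,
                      seed = seed)
  subjects <- generate_subjects(cc)
  effects <- lapply(config$effects, function(e)
    effect_spec(e$metabolite, e$group, e$effect,
                isTRUE(e$levodopa_only)))
  snp_specs <- lapply(config$snps, function(s) snp_spec(s$snp_id, s$maf))
  G <- generate_genotypes(subjects, snp_specs, seed = seed + 1L)
  snp_eff <- Filter(Negate(is.null), lapply(config$snps, function(s)
    if (!is.null(s$effect_hcy))
      list(snp = s$snp_id, metabolite = "Hcy", effect = s$effect_hcy)))
  assay <- generate_raw_assay(subjects, effects, genotypes = G,
                              snp_effects = snp_eff, seed = seed + 2L)
  write_tsv(subjects, file.path(config$out, "subjects.tsv"))
  write_tsv(assay$wells, file.path(config$out, "raw_assay.tsv"))
  write_genotypes_tsv(G, file.path(config$out, "genotypes.tsv"))
  outputs$simulate <- c("subjects.tsv", "raw_assay.tsv", "genotypes.tsv")

  # preprocess
  pm <- preprocess_assay(assay, subjects)
  zdf <- cbind(subject_id = rownames(pm$z), as.data.frame(pm$z))
  write_tsv(zdf, f <- file.path(config$out, "processed_matrix.tsv"))
  meta <- lapply(pm$meta, function(m) m[setdiff(names(m), "calibration")])
  jsonlite::write_json(meta, file.path(config$out, "processed_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs$preprocess <- c("processed_matrix.tsv", "processed_meta.json")

  # differential
  diff_tab <- run_differential(pm, subjects)
  diff_merged <- run_differential(pm, subjects,
                                  merge_groups = config$merge_groups)
  write_tsv(diff_tab, file.path(config$out, "differential.tsv"))
  write_tsv(diff_merged, file.path(config$out, "differential_merged.tsv"))
  outputs$differential <- c("differential.tsv", "differential_merged.tsv")

  # SNP association with Hcy/betaine (inheritance model by BIC),
  # excluding acute-levodopa samples
  Gf <- filter_rare_snps(G)
  covs <- data.frame(sex = as.integer(subjects$sex == "F"),
                     age = subjects$age,
                     log_pmi = log(subjects$pmi_hours),
                     log_storage = log(subjects$storage_years))
  lmask <- subjects$levodopa_exposed == 1L
  snp_hcy <- snp_metabolite_assoc(Gf, pm$z[, "Hcy"], covs, lmask, "hcy")
  snp_bet <- snp_metabolite_assoc(Gf, pm$z[, "betaine"], covs, lmask,
                                  "betaine")
  snp_assoc <- rbind(snp_hcy, snp_bet)
  write_tsv(snp_assoc, file.path(config$out, "snp_assoc.tsv"))
  outputs$snp <- "snp_assoc.tsv"

  # vitamin associations with Hcy and betaine
  vits <- setdiff(colnames(pm$z), c("Hcy", "betaine", "DOPA", pm$excluded))
  vit_hcy <- run_covariate_assoc(pm$z[, "Hcy"], pm$z[, vits, drop = FALSE],
                                 subjects, pm)
  vit_hcy$response <- "hcy"
  vit_bet <- run_covariate_assoc(pm$z[, "betaine"],
                                 pm$z[, vits, drop = FALSE], subjects, pm)
  vit_bet$response <- "betaine"
  vit_assoc <- rbind(vit_hcy, vit_bet)
  write_tsv(vit_assoc, file.path(config$out, "vitamin_assoc.tsv"))

  # composite scores
  sets <- suppressWarnings(build_risk_sets(
    snp_assoc, vit_assoc,
    snp_q_threshold = config$fdr$genomic,
    vitamin_fdr_threshold = config$fdr$metabolomic))
  sc <- composite_scores(Gf, pm$z, sets)
  cmp <- do.call(rbind, lapply(c("snp_risk", "snp_protect", "vitamin_risk"),
                               function(s) {
    d <- compare_to_controls(sc[[s]], subjects$group)
    d$score <- s
    d
  }))
  write_tsv(sc, file.path(config$out, "scores.tsv"))
  write_tsv(cmp, file.path(config$out, "score_comparison.tsv"))
  outputs$scores <- c("scores.tsv", "score_comparison.tsv")

  # GP classification of the configured target pair
  tgt <- config$gp$target
  sel <- if (identical(tgt, c("PD-D", "PD-ND")))
    subjects$group %in% c("PD-D", "PD-MCI", "PD-CN")
  else subjects$group %in% tgt
  labels <- as.integer(subjects$group[sel] == tgt[1])
  feats <- gp_features(pm$z[sel, setdiff(colnames(pm$z), "DOPA"),
                            drop = FALSE],
                       Gf[sel, , drop = FALSE])
  gcfg <- gp_config(scaled_down = isTRUE(config$gp$scaled_down),
                    seed = seed + 3L)
  gfit <- gp_evolve(feats, labels, gcfg)
  gp_out <- list(expression = gfit$expression, fitness = gfit$fitness,
                 acc_pos = gfit$acc_pos, acc_neg = gfit$acc_neg,
                 n_operands = gfit$n_operands, target = tgt)
  jsonlite::write_json(gp_out, file.path(config$out, "gp_result.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs$gp <- "gp_result.json"

  # manifest
  cfg_file <- file.path(config$out, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(config$out, manifest = manifest)
}

#' Summarize a completed pipeline run
#'
#' Writes heatmap-style and score-comparison summary tables from the stage
#' outputs present in a run directory; missing stages produce a partial
#' report with warnings.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return named list of summary data.frames (also written as TSV).
#' @export
write_report <- function(run_dir) {
  out <- list()
  dfile <- file.path(run_dir, "differential.tsv")
  if (file.exists(dfile)) {
    d <- read_tsv(dfile)
    heat <- stats::reshape(d[, c("response", "term", "beta")],
                           idvar = "response", timevar = "term",
                           direction = "wide")
    names(heat) <- sub("^beta\\.", "", names(heat))
    sig <- d[!is.na(d$fdr) & d$fdr <= 0.05, ]
    if (nrow(sig) == 0)
      message("report: no significant differential findings")
    write_tsv(heat, file.path(run_dir, "report_heatmap.tsv"))
    out$heatmap <- heat
  } else warning("differential stage output missing", call. = FALSE)
  sfile <- file.path(run_dir, "score_comparison.tsv")
  if (file.exists(sfile)) {
    s <- read_tsv(sfile)
    write_tsv(s, file.path(run_dir, "report_scores.tsv"))
    out$scores <- s
  } else warning("score stage output missing", call. = FALSE)
  gfile <- file.path(run_dir, "gp_result.json")
  if (file.exists(gfile)) out$gp <- jsonlite::read_json(gfile)
  invisible(out)
}
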