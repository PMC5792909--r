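#' Pipeline configuration
#'
#' Assembles the configuration for the staged command-line pipeline from
#' defaults, an optional YAML file, and direct overrides (highest
#' precedence). Thresholds are validated; the seed always has an explicit
#' value and is recorded in every stage manifest.
#'
#' @param out_dir output directory (created if needed)
#' @param config_file optional YAML file of settings
#' @param ... overrides: `n_samples`, `n_validation`, `k`, `alpha`,
#'   `min_call_rate`, `min_maf`, `r2_prune`, `r2_link`, `window_bp`, `seed`,
#'   and input paths `genotypes`, `phenotypes`, `anchors` (defaults point at
#'   the simulate stage's outputs inside `out_dir`).
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, config_file = NULL, ...) {
  cfg <- list(out_dir = out_dir,
              n_samples = 7795L, n_validation = 779L,
              k = 10L, alpha = 0.01,
              min_call_rate = 0.98, min_maf = 0.05,
              r2_prune = 0.2, r2_link = 0.98, window_bp = 100000L,
              seed = 1L,
              genotypes = NULL, phenotypes = NULL, anchors = NULL)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    user <- yaml::read_yaml(config_file)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, TRUE)]
  cfg[names(dots)] <- dots
  if (is.null(cfg$genotypes)) cfg$genotypes <- file.path(out_dir, "genotypes.vcf")
  if (is.null(cfg$phenotypes)) cfg$phenotypes <- file.path(out_dir, "phenotypes.tsv")
  if (is.null(cfg$anchors)) cfg$anchors <- file.path(out_dir, "anchors.tsv")
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$k >= 2,
            cfg$r2_prune >= 0, cfg$r2_prune <= 1,
            cfg$r2_link >= 0, cfg$r2_link <= 1,
            cfg$window_bp >= 0, cfg$min_call_rate > 0, cfg$min_call_rate <= 1,
            cfg$min_maf >= 0, cfg$min_maf <= 0.5)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  # record paths relative to the output directory so that runs are
  # reproducible byte-for-byte regardless of where they live
  strip_dir <- function(x) {
    if (is.character(x)) {
      pref <- paste0(sub("/+$", "", cfg$out_dir), "/")
      ifelse(startsWith(x, pref), substring(x, nchar(pref) + 1L), x)
    } else if (is.list(x)) lapply(x, strip_dir) else x
  }
  inputs <- strip_dir(inputs)
  outputs <- strip_dir(outputs)
  man <- list(stage = stage,
              package = "lipidgrs",
              version = as.character(utils::packageVersion("lipidgrs")),
              seed = cfg$seed,
              parameters = cfg[c("n_samples", "n_validation", "k", "alpha",
                                 "min_call_rate", "min_maf", "r2_prune",
                                 "r2_link", "window_bp")],
              inputs = inputs, outputs = outputs)
  path <- file.path(cfg$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = 10)
  path
}

count_rows <- function(path) length(readLines(path)) - 1L

require_inputs <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
}

stage_simulate <- function(cfg) {
  sc <- kare_like_scenario(seed = cfg$seed, n = cfg$n_samples)
  n <- cfg$n_samples
  nv <- min(cfg$n_validation, n - cfg$k)
  perm <- with_seed(derive_seed(cfg$seed, 555001L), sample.int(n))
  split <- data.frame(sample_id = sc$genotypes$sample_ids,
                      set = "selection", stringsAsFactors = FALSE)
  if (nv > 0) split$set[perm[seq_len(nv)]] <- "validation"
  out <- c(genotypes = file.path(cfg$out_dir, "genotypes.vcf"),
           phenotypes = file.path(cfg$out_dir, "phenotypes.tsv"),
           anchors = file.path(cfg$out_dir, "anchors.tsv"),
           split = file.path(cfg$out_dir, "split.tsv"))
  write_vcf(sc$genotypes, out[["genotypes"]])
  write_phenotypes(sc$phenotypes, out[["phenotypes"]])
  write_anchors(sc$anchors, out[["anchors"]])
  write.table(split, out[["split"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "simulate", inputs = list(),
                 outputs = lapply(as.list(out), function(p)
                   list(path = p, rows = count_rows(p))))
  invisible(out)
}

stage_qc <- function(cfg) {
  require_inputs(cfg$genotypes, cfg$anchors)
  g <- read_vcf(cfg$genotypes)
  anchors <- read_anchors(cfg$anchors)
  n0 <- ncol(g$dosage)
  cr <- filter_call_rate(g, cfg$min_call_rate)
  mf <- filter_maf(cr$genotypes, cfg$min_maf)
  g2 <- mf$genotypes
  windowed <- window_filter(g2$snps, anchors, cfg$window_bp)
  pruned <- prune_by_ld(windowed, g2, r2_max = cfg$r2_prune)
  linked <- link_to_anchors(pruned, g2, anchors, r2_min = cfg$r2_link)
  counts <- c(input = n0, call_rate = ncol(cr$genotypes$dosage),
              maf = ncol(g2$dosage), window = nrow(windowed),
              prune = nrow(pruned), link = nrow(linked))
  message("QC/LD cascade SNP counts: ",
          paste(names(counts), counts, sep = "=", collapse = " -> "))
  panel <- subset_genotypes(g2, snps = linked$id)
  out <- c(genotypes = file.path(cfg$out_dir, "qc_genotypes.tsv"),
           snps = file.path(cfg$out_dir, "qc_snps.tsv"),
           report = file.path(cfg$out_dir, "qc_report.json"))
  write_dosage_tsv(panel, out[["genotypes"]])
  snp_out <- panel$snps
  snp_out$maf <- sprintf("%.10g", snp_out$maf)
  write.table(snp_out, out[["snps"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = cfg[c("min_call_rate", "min_maf", "r2_prune",
                            "r2_link", "window_bp")],
         cascade_snp_counts = as.list(counts),
         samples_removed = cr$report$samples_removed,
         snps_removed_call_rate = cr$report$snps_removed,
         snps_removed_maf = mf$report$snps_removed),
    out[["report"]], auto_unbox = TRUE, pretty = TRUE, digits = 10)
  write_manifest(cfg, "qc",
                 inputs = list(genotypes = cfg$genotypes, anchors = cfg$anchors),
                 outputs = lapply(as.list(out), function(p) list(path = p)))
  invisible(out)
}

read_qc_panel <- function(cfg) {
  gpath <- file.path(cfg$out_dir, "qc_genotypes.tsv")
  spath <- file.path(cfg$out_dir, "qc_snps.tsv")
  require_inputs(gpath, spath, cfg$phenotypes)
  snps <- read.delim(spath, stringsAsFactors = FALSE,
                     colClasses = list(chrom = "character"))
  g <- read_dosage_tsv(gpath, snps = snps)
  ph <- read_phenotypes(cfg$phenotypes)
  split_path <- file.path(cfg$out_dir, "split.tsv")
  split <- if (file.exists(split_path))
    read.delim(split_path, stringsAsFactors = FALSE) else NULL
  list(genotypes = g, phenotypes = ph, split = split)
}

selection_samples <- function(panel) {
  if (is.null(panel$split)) return(panel$phenotypes$sample_id)
  panel$split$sample_id[panel$split$set == "selection"]
}

stage_associate <- function(cfg) {
  panel <- read_qc_panel(cfg)
  ids <- intersect(selection_samples(panel), panel$genotypes$sample_ids)
  res <- associate_panel(subset_genotypes(panel$genotypes, samples = ids),
                         panel$phenotypes)
  out <- file.path(cfg$out_dir, "association.tsv")
  fmt <- res
  for (v in c("slope", "se", "t", "p")) fmt[[v]] <- sprintf("%.10g", fmt[[v]])
  write.table(fmt, out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "associate",
                 inputs = list(phenotypes = cfg$phenotypes),
                 outputs = list(association = list(path = out, rows = nrow(res))))
  invisible(c(association = out))
}

stage_select <- function(cfg) {
  panel <- read_qc_panel(cfg)
  ids <- intersect(selection_samples(panel), panel$genotypes$sample_ids)
  sel <- run_cv_selection(subset_genotypes(panel$genotypes, samples = ids),
                          panel$phenotypes, k = cfg$k, alpha = cfg$alpha,
                          seed = cfg$seed)
  long <- expand.grid(snp = rownames(sel$p_matrix),
                      fold = colnames(sel$p_matrix),
                      trait = dimnames(sel$p_matrix)[[3L]],
                      stringsAsFactors = FALSE)
  long$p <- sprintf("%.10g", sel$p_matrix[as.matrix(long[, 1:3])])
  long$slope <- sprintf("%.10g", sel$slope_matrix[as.matrix(long[, 1:3])])
  long$passed <- sel$p_matrix[as.matrix(long[, 1:3])] <= cfg$alpha
  out <- c(report = file.path(cfg$out_dir, "selection_pvalues.tsv"),
           selected = file.path(cfg$out_dir, "selected_snps.tsv"))
  write.table(long, out[["report"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(snp = sel$selected), out[["selected"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "select",
                 inputs = list(phenotypes = cfg$phenotypes),
                 outputs = list(report = list(path = out[["report"]]),
                                selected = list(path = out[["selected"]],
                                                n_selected = length(sel$selected))))
  invisible(out)
}

stage_grs <- function(cfg) {
  panel <- read_qc_panel(cfg)
  selpath <- file.path(cfg$out_dir, "selected_snps.tsv")
  require_inputs(selpath)
  selected <- read.delim(selpath, stringsAsFactors = FALSE)$snp
  out <- c(weights = file.path(cfg$out_dir, "weights.tsv"),
           scores = file.path(cfg$out_dir, "scores.tsv"),
           trend = file.path(cfg$out_dir, "trend.json"))
  if (!length(selected)) {
    writeLines("snp\ttrait\torientation\trisk_allele\tweight\tslope", out[["weights"]])
    writeLines("sample_id\ttrait\twgrs\tquartile", out[["scores"]])
    jsonlite::write_json(list(note = "no SNPs selected"), out[["trend"]],
                         auto_unbox = TRUE, pretty = TRUE)
    write_manifest(cfg, "grs", inputs = list(selected = selpath),
                   outputs = lapply(as.list(out), function(p) list(path = p)))
    return(invisible(out))
  }
  ids_sel <- intersect(selection_samples(panel), panel$genotypes$sample_ids)
  g_sel <- subset_genotypes(panel$genotypes, samples = ids_sel)
  ph <- panel$phenotypes
  ph_sel <- ph[ph$sample_id %in% ids_sel, ]
  traits <- c("tc_hdl_ratio", "log_tg_hdl_ratio")
  assoc <- associate_panel(subset_genotypes(g_sel, snps = selected), ph_sel,
                           traits = traits)
  w <- build_weights(assoc, selected, snps = panel$genotypes$snps)
  score_rows <- list(); trend_out <- list()
  groups <- function(p) list(all = rep(TRUE, nrow(p)), male = p$sex == 0,
                             female = p$sex == 1)
  sets <- list(selection = ids_sel)
  if (!is.null(panel$split)) {
    idv <- intersect(panel$split$sample_id[panel$split$set == "validation"],
                     panel$genotypes$sample_ids)
    if (length(idv) >= 4L) sets$validation <- idv
  }
  for (set_name in names(sets)) {
    ids <- sets[[set_name]]
    gset <- subset_genotypes(panel$genotypes, samples = ids)
    pset <- ph[match(intersect(ids, ph$sample_id), ph$sample_id), ]
    for (tr in traits) {
      sc <- compute_wgrs(gset, w, tr)[pset$sample_id]
      labs <- quartile_bin(pset[[tr]])
      score_rows[[paste(set_name, tr)]] <-
        data.frame(sample_id = pset$sample_id, set = set_name, trait = tr,
                   wgrs = sprintf("%.10g", sc), quartile = labs,
                   stringsAsFactors = FALSE)
      for (gname in names(groups(pset))) {
        selrows <- groups(pset)[[gname]]
        if (sum(selrows) < 4L) next
        t <- trend_fit(sc[selrows], quartile_bin(pset[[tr]][selrows]),
                       group = gname)
        trend_out[[length(trend_out) + 1L]] <-
          list(set = set_name, trait = tr, group = gname,
               quartile_means = t$quartile_means, slope = t$slope,
               p_value = t$p_value, r_squared = t$r_squared,
               r_squared_individual = t$r_squared_individual, n = t$n)
      }
    }
  }
  wfmt <- as.data.frame(w)
  wfmt$weight <- sprintf("%.10g", wfmt$weight)
  wfmt$slope <- sprintf("%.10g", wfmt$slope)
  write.table(wfmt, out[["weights"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, score_rows), out[["scores"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(trend_out, out[["trend"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  write_manifest(cfg, "grs", inputs = list(selected = selpath),
                 outputs = lapply(as.list(out), function(p) list(path = p)))
  invisible(out)
}

#' Run pipeline stages
#'
#' Executes one stage of the analysis pipeline — `simulate` (write a
#' synthetic KARE-like cohort), `qc` (call-rate and MAF filters plus the
#' window/prune/link LD cascade), `associate` (per-SNP additive scan),
#' `select` (cross-validation consistency selection), `grs` (weights,
#' scores and quartile trends) — or `all` of them in order. Each stage
#' writes its outputs and a JSON run manifest (parameters, seed, package
#' version, input/output files) into `cfg$out_dir`; a failing stage removes
#' the files it had started writing.
#'
#' @param stage one of "simulate", "qc", "associate", "select", "grs", "all"
#' @param cfg a [pipeline_config()]
#' @return named character vector of output paths, invisibly
#' @export
pipeline_run <- function(stage = c("all", "simulate", "qc", "associate",
                                   "select", "grs"), cfg) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "qc", "associate", "select", "grs") else stage
  fns <- list(simulate = stage_simulate, qc = stage_qc,
              associate = stage_associate, select = stage_select,
              grs = stage_grs)
  out <- character(0)
  for (s in stages) {
    before <- list.files(cfg$out_dir, full.names = TRUE)
    res <- tryCatch(fns[[s]](cfg), error = function(e) {
      created <- setdiff(list.files(cfg$out_dir, full.names = TRUE), before)
      unlink(created)
      stop("stage '", s, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out <- c(out, res)
  }
  invisible(out)
}
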