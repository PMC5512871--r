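#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/` (empty to list all).
#' @return Full path.
#' @examples
#' retroclock_example("fv_flerv_timescales.tsv")
#' @export
retroclock_example <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "retroclock")))
  }
  p <- system.file("extdata", file, package = "retroclock")
  if (!nzchar(p)) stop("no packaged example file: ", file)
  p
}

#' Load the packaged foamy-virus lineage timescale table
#'
#' Host-calibrated per-lineage substitution estimates and divergence times
#' for nodes along the mammalian foamy virus focal lineage (nodes I-IX,
#' calibrated from host divergence dates under the FV-host co-speciation
#' assumption) and the three deep uncalibrated nodes (X-XII) dated by
#' power-law extrapolation. Columns: `node`, `s_median`, `s_low`, `s_high`
#' (substitutions/site), `t_median`, `t_low`, `t_high` (Myr; `NA` for the
#' uncalibrated nodes), `calibrated` (logical).
#'
#' @return Data frame of 12 rows.
#' @examples
#' tab <- fv_timescales()
#' cal <- tab[tab$calibrated, ]
#' fit_power_law(cal$s_median, cal$t_median)
#' @export
fv_timescales <- function() {
  df <- utils::read.delim(retroclock_example("fv_flerv_timescales.tsv"),
                          stringsAsFactors = FALSE)
  df$calibrated <- as.logical(df$calibrated)
  df
}

.stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

.file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

#' Run a configured analysis pipeline
#'
#' Executes the stages named in a YAML (or list) configuration in order,
#' writing machine-readable outputs and a run manifest into `out_dir`.
#' Recognised stages and their parameters:
#' \describe{
#'   \item{simulate}{`scenario` one of `cophylogeny`, `tdrp_posterior`,
#'     `tn93_pair`, `erv_contig`; plus the matching generator's parameters.}
#'   \item{tdrp}{`trees` (Newick path), `focal`, `calib` (TSV), `specs`
#'     (TSV), `targets` (TSV), `t_sampling`, `seed`.}
#'   \item{ltr_date}{`pair` (FASTA of the two aligned LTRs), `rate` (one or
#'     more substitutions/site/year).}
#'   \item{cospeciation}{`host`, `parasite` (Newick paths), `assoc` (TSV),
#'     `n`, `seed`, optional `collapse_support` applied to both trees.}
#'   \item{annotate}{`contig` (FASTA), `min_len`, `min_identity`,
#'     `max_gap`.}
#' }
#'
#' @param config Path to a YAML config, or an equivalent named list. The
#'   top-level key `stages` lists stage names to run; each stage has its own
#'   block.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; outputs and `manifest.json` are written
#'   there.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_text <- NULL
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_text <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- yaml::yaml.load(cfg_text)
  } else {
    cfg_text <- yaml::as.yaml(config)
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given (out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- unlist(config$stages)
  if (!length(stages)) stop("config lists no stages")
  inputs <- character(0)
  summary <- list()
  for (stage in stages) {
    sc <- config[[stage]]
    if (is.null(sc)) stop(sprintf("stage '%s': no configuration block", stage))
    summary[[stage]] <- switch(
      stage,
      simulate = .stage_error("simulate", .run_simulate(sc, out_dir)),
      tdrp = .stage_error("tdrp", {
        inputs <- c(inputs, sc$trees, sc$calib, sc$specs, sc$targets)
        .run_tdrp(sc, out_dir)
      }),
      ltr_date = .stage_error("ltr_date", {
        inputs <- c(inputs, sc$pair)
        .run_ltr_date(sc, out_dir)
      }),
      cospeciation = .stage_error("cospeciation", {
        inputs <- c(inputs, sc$host, sc$parasite, sc$assoc)
        .run_cospeciation(sc, out_dir)
      }),
      annotate = .stage_error("annotate", {
        inputs <- c(inputs, sc$contig)
        .run_annotate(sc, out_dir)
      }),
      stop(sprintf("unknown stage '%s'", stage))
    )
  }
  tf <- tempfile(); writeLines(cfg_text, tf)
  manifest <- list(
    tool = "retroclock",
    version = as.character(utils::packageVersion("retroclock")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_hash = unname(tools::md5sum(tf)),
    inputs = .file_digest(unique(inputs)),
    stages = stages,
    parameters = config[stages]
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

.require_files <- function(paths) {
  for (p in paths) if (!file.exists(p)) stop("missing input file: ", p)
}

.run_simulate <- function(sc, out_dir) {
  scen <- sc$scenario
  if (is.null(scen)) stop("simulate stage needs 'scenario'")
  seed <- if (is.null(sc$seed)) 1L else as.integer(sc$seed)
  if (scen == "cophylogeny") {
    sim <- simulate_cophylogeny(n_hosts = sc$n_hosts %||% 10L,
                                switch_prob = sc$switch_prob %||% 0,
                                loss_prob = sc$loss_prob %||% 0, seed = seed)
    write_newick(sim$host, file.path(out_dir, "host.nwk"))
    write_newick(sim$parasite, file.path(out_dir, "parasite.nwk"))
    writeLines(c("parasite_tip\thost_tip",
                 paste(names(sim$assoc), sim$assoc, sep = "\t")),
               file.path(out_dir, "assoc.tsv"))
    jsonlite::write_json(list(true_cospeciations = sim$true_cospeciations),
                         file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    list(scenario = scen, n_parasite_tips = length(sim$assoc),
         true_cospeciations = sim$true_cospeciations)
  } else if (scen == "tdrp_posterior") {
    sim <- simulate_tdrp_posterior(
      alpha = sc$alpha %||% 2.61, beta = sc$beta %||% 1.63,
      S_nodes = unlist(sc$S_nodes),
      rel_noise_sd = sc$rel_noise_sd %||% 0.1,
      n_trees = sc$n_trees %||% 100L, seed = seed)
    write_newick(sim$trees, file.path(out_dir, "trees.nwk"))
    utils::write.table(sim$calibration, file.path(out_dir, "calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_node_specs(sim$specs, file.path(out_dir, "specs.tsv"))
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(scenario = scen, n_trees = length(sim$trees))
  } else if (scen == "tn93_pair") {
    pair <- simulate_tn93_pair(d = sc$d %||% 0.05, L = sc$L %||% 1000L,
                               seed = seed)
    writeLines(c(">ltr5", pair[1], ">ltr3", pair[2]),
               file.path(out_dir, "pair.fasta"))
    list(scenario = scen, L = nchar(pair[1]))
  } else if (scen == "erv_contig") {
    sim <- simulate_erv_contig(ltr_len = sc$ltr_len %||% 400L,
                               internal_len = sc$internal_len %||% 6000L,
                               tsd_len = sc$tsd_len %||% 4L,
                               ltr_divergence = sc$ltr_divergence %||% 0,
                               flank_len = sc$flank_len %||% 2000L,
                               seed = seed)
    writeLines(c(paste0(">", sim$id), sim$contig),
               file.path(out_dir, "contig.fasta"))
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(scenario = scen, contig_length = nchar(sim$contig))
  } else stop("unknown simulate scenario: ", scen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_tdrp <- function(sc, out_dir) {
  .require_files(c(sc$trees, sc$calib, sc$specs, sc$targets))
  trees <- parse_newick(file = sc$trees)
  calib <- read_calibration(sc$calib)
  specs <- read_node_specs(sc$specs)
  targets <- read_node_specs(sc$targets)
  est <- posterior_dating(trees, focal_tip = sc$focal, calibration = calib,
                          calib_specs = specs, target_specs = targets,
                          t_sampling = sc$t_sampling %||% "median",
                          seed = sc$seed %||% 1L)
  utils::write.table(est$summary, file.path(out_dir, "tdrp_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(est$summary, file.path(out_dir, "tdrp_estimates.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  est$summary
}

.run_ltr_date <- function(sc, out_dir) {
  .require_files(sc$pair)
  pair <- read_aligned_pair(sc$pair)
  tn <- tn93_distance(as.character(pair[[1]]), as.character(pair[[2]]))
  rate <- as.numeric(unlist(sc$rate))
  age <- ltr_age(tn$d, rate)
  out <- list(d = tn$d, P1 = tn$P1, P2 = tn$P2, Q = tn$Q, L = tn$L,
              rate = rate, age_Myr = age$age_myr)
  jsonlite::write_json(out, file.path(out_dir, "ltr_age.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

.run_cospeciation <- function(sc, out_dir) {
  .require_files(c(sc$host, sc$parasite, sc$assoc))
  host <- parse_newick(file = sc$host)
  parasite <- parse_newick(file = sc$parasite)
  if (!is.null(sc$collapse_support)) {
    host <- collapse_low_support(host, sc$collapse_support)
    parasite <- collapse_low_support(parasite, sc$collapse_support)
  }
  tg <- tanglegram(host, parasite, read_associations(sc$assoc))
  test <- random_tip_mapping_test(tg, N = sc$n %||% 500L, seed = sc$seed %||% 1L)
  out <- list(observed = test$observed,
              n_parasite_internal = tg$parasite$Nnode,
              N = test$N, k = test$k, p_value = test$p_value,
              p_display = test$p_display, seed = test$seed)
  jsonlite::write_json(out, file.path(out_dir, "cospeciation.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

.run_annotate <- function(sc, out_dir) {
  .require_files(sc$contig)
  fa <- Biostrings::readDNAStringSet(sc$contig)
  res <- list()
  for (i in seq_along(fa)) {
    id <- sub("\\s.*", "", names(fa)[i])
    ann <- annotate_contig(as.character(fa[[i]]),
                           min_len = sc$min_len %||% 200L,
                           min_identity = sc$min_identity %||% 80,
                           max_gap = sc$max_gap %||% 25000L)
    write_annotation_bed(ann, id, file.path(out_dir, paste0(id, "_ltr.bed")))
    write_annotation_gff3(ann, id, file.path(out_dir, paste0(id, ".gff3")))
    res[[id]] <- list(n_ltr_pairs = nrow(ann$ltr_pairs),
                      n_tsds = sum(!vapply(ann$tsds, is.null, logical(1))))
  }
  res
}
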