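#' Validated run configuration
#'
#' Collects input paths, role definitions and all stage parameters, with
#' defaults equal to the package's standard analysis values. Unknown keys
#' are rejected before any stage runs.
#'
#' @param ... named configuration entries; see Details.
#' @details Recognised keys: `vcf`, `sample_map`, `mask`, `mask_one_based`,
#'   `outgroup`, `roles` (list with P1/P2/P3 species vectors), `filters`
#'   (list passed to [filter_params()]), `blocks`, `window_snps`,
#'   `max_window_bp`, `tail_q`, `gen_time`, `mu`, `accessible_length`,
#'   `chrom_lengths`, `nj_window_bp`, `bootstrap`, `seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    vcf = NULL, sample_map = NULL, mask = NULL, mask_one_based = TRUE,
    outgroup = "ANC", roles = NULL, filters = list(),
    blocks = JACKKNIFE_BLOCKS, window_snps = WINDOW_SNPS,
    max_window_bp = MAX_WINDOW_BP, tail_q = TAIL_Q,
    gen_time = GEN_TIME, mu = MU, accessible_length = NULL,
    chrom_lengths = NULL, nj_window_bp = 1e5, bootstrap = 100L, seed = 1L)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!inherits(cfg$filters, "filter_params"))
    cfg$filters <- do.call(filter_params, as.list(cfg$filters))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose top-level keys follow [run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_header <- function(cfg, stage) {
  sprintf("# introgrescan %s | stage=%s | seed=%d | blocks=%d window_snps=%d max_window_bp=%d tail_q=%g gen_time=%g mu=%g",
          as.character(utils::packageVersion("introgrescan")), stage,
          as.integer(cfg$seed), cfg$blocks, cfg$window_snps,
          cfg$max_window_bp, cfg$tail_q, cfg$gen_time, cfg$mu)
}

write_stage_tsv <- function(df, path, cfg, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(cfg, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes filter -> mask -> polarize and then the requested analysis
#' stages in order, writing each stage's table to `out_dir` with a header
#' carrying the package version, seed and parameter echo, plus a run log of
#' per-stage site and trio counts.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("dtrios", "dinvestigate", "split_times",
#'   "njtree")`.
#' @return (invisibly) a list of stage results and output paths.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("dtrios", "dinvestigate")) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages,
                      c("dtrios", "dinvestigate", "split_times", "njtree"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  t <- run_stage("read", read_vcf(cfg$vcf))
  map <- run_stage("read", read_sample_map(cfg$sample_map))
  log$sites_in <- n_sites(t)

  filt <- run_stage("filter", apply_site_filters(t, cfg$filters))
  t <- filt$table
  write_filter_log(filt$log, file.path(out_dir, "filter_log.tsv"))
  log$sites_filtered <- n_sites(t)

  if (!is.null(cfg$mask)) {
    mask <- read_region_mask(cfg$mask, one_based = cfg$mask_one_based)
    t <- run_stage("mask", mask_regions(t, mask))
  }
  log$sites_masked <- n_sites(t)

  t <- run_stage("polarize", polarize(t, cfg$outgroup))
  res <- list(table = t, log = log, paths = character(0))

  members_of <- function(role_species)
    map$sample[map$species %in% role_species]

  if ("dtrios" %in% stages) {
    tr <- run_stage("dtrios", {
      roles <- cfg$roles
      roles$outgroup <- map$species[map$sample == cfg$outgroup][1]
      dtrios(t, map, roles, blocks = cfg$blocks, seed = cfg$seed)
    })
    p <- file.path(out_dir, "trios.tsv")
    write_stage_tsv(tr, p, cfg, "dtrios")
    log$trios <- nrow(tr)
    res$dtrios <- tr
    res$paths <- c(res$paths, p)
  }
  if ("dinvestigate" %in% stages) {
    wres <- run_stage("dinvestigate", {
      roles <- list(P1 = members_of(cfg$roles$P1),
                    P2 = members_of(cfg$roles$P2),
                    P3 = members_of(cfg$roles$P3),
                    outgroup = cfg$outgroup)
      w <- fdm_windows(t, roles, window_snps = cfg$window_snps)
      w <- drop_oversize(w, max_bp = cfg$max_window_bp)
      rep <- candidate_threshold(w, q = cfg$tail_q)
      adj <- adjacency_stats(rep, w)
      list(windows = w, report = rep, adjacency = adj)
    })
    p <- file.path(out_dir, "fdm_windows.tsv")
    write_stage_tsv(cbind(wres$windows,
                          candidate = wres$report$candidate),
                    p, cfg, "dinvestigate")
    adf <- data.frame(total_windows = wres$report$N,
                      candidate_windows = wres$report$k,
                      candidate_percent = wres$report$percent,
                      threshold = wres$report$threshold,
                      observed_adjacent = wres$adjacency$observed,
                      expected_adjacent = wres$adjacency$expected,
                      deviation = wres$adjacency$deviation)
    p2 <- file.path(out_dir, "adjacency.tsv")
    write_stage_tsv(adf, p2, cfg, "dinvestigate")
    log$windows <- wres$report$N
    res$dinvestigate <- wres
    res$paths <- c(res$paths, p, p2)
  }
  if ("split_times" %in% stages) {
    st <- run_stage("split_times", {
      split_time_estimate(t, members_of(cfg$roles$P1),
                          members_of(cfg$roles$P2),
                          chrom_lengths = cfg$chrom_lengths,
                          gen_time = cfg$gen_time, mu = cfg$mu)
    })
    p <- file.path(out_dir, "split_times.tsv")
    write_stage_tsv(data.frame(da = st$da, da_lower = st$da_lower,
                               da_upper = st$da_upper,
                               t_lower = st$t_lower, t_upper = st$t_upper),
                    p, cfg, "split_times")
    res$split_times <- st
    res$paths <- c(res$paths, p)
  }
  if ("njtree" %in% stages) {
    nj <- run_stage("njtree", {
      wd <- window_distances(t, window_bp = cfg$nj_window_bp)
      bootstrap_support(wd, outgroup = cfg$outgroup, B = cfg$bootstrap,
                        seed = cfg$seed)
    })
    p <- file.path(out_dir, "tree.nwk")
    ape::write.tree(nj, file = p)
    res$njtree <- nj
    res$paths <- c(res$paths, p)
  }
  writeLines(c(stage_header(cfg, "log"),
               paste(names(log), unlist(log), sep = "\t")),
             file.path(out_dir, "run_log.tsv"))
  res$log <- log
  invisible(res)
}
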