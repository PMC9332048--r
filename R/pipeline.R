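# Pipeline orchestration: a single YAML configuration with per-module
# namespaces drives the subcommands synth / extract / filter / classify /
# scan / cluster / profile / support / export. Every output artefact
# carries a header with the master seed and a hash of the configuration.

#' Default pipeline configuration
#'
#' Defaults equal the method's stated constants: membership Z 5.0, scan
#' Z0 6.0, indel penalty 20, minimum class volume 100, scan window
#' L1 + 50, overlap fraction 0.10, run thresholds m0 {A:13,T:12,C:5,G:5},
#' GC range 0.29 to 0.37.
#'
#' @return nested configuration list.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    paths = list(workdir = "ppscan_work", genome = NULL, genes = NULL),
    filters = list(max_base_frac = 0.60, max_n = 1L,
                   m0_A = 13L, m0_T = 12L, m0_C = 5L, m0_G = 5L,
                   gc_min = 0.29, gc_max = 0.37),
    ga = list(pop_size = 20L, generations = 200L, p_insert = 0.1,
              p_delete = 0.1, tol = 1e-3, patience = 10L,
              sample_size = 1000L, max_l1 = 650L),
    classify = list(z_threshold = 5.0, min_class_size = 100L,
                    n_shuffles = 1000L, max_classes = 50L),
    scan = list(z0 = 6.0, stride = 1L, overlap_fraction = 0.10,
                variants = c("identity", "reverse_complement"),
                max_n_frac = 0.10, d = 20, window_slack = 50L,
                null_windows = 10000L),
    cluster = list(d = 20, n_mix = 1000L, cut = 0.8, squared = FALSE),
    synth = list()  # overrides for synth_spec()
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Reads YAML and merges it over [pipeline_defaults()].
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return configuration list with attribute \code{hash} (MD5 of the
#'   merged configuration).
#' @export
read_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  cfg
}

config_filter_params <- function(cfg) {
  f <- cfg$filters
  filter_params(max_base_frac = f$max_base_frac, max_n = f$max_n,
                m0 = c(A = f$m0_A, T = f$m0_T, C = f$m0_C, G = f$m0_G),
                gc_min = f$gc_min, gc_max = f$gc_max)
}

config_scan <- function(cfg) {
  s <- cfg$scan
  scan_config(z0 = s$z0, stride = s$stride,
              overlap_fraction = s$overlap_fraction, variants = s$variants,
              max_n_frac = s$max_n_frac, gaps = gap_params(s$d),
              window_slack = s$window_slack, null_windows = s$null_windows)
}

art <- function(cfg, ...) file.path(cfg$paths$workdir, ...)

provenance <- function(cfg)
  sprintf("ppscan seed=%s config=%s", cfg$seed, attr(cfg, "hash") %||% "NA")

write_tsv_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance(cfg)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_artifact <- function(path)
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)

need_artifact <- function(cfg, file, producer) {
  p <- art(cfg, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run 'ppscan ", producer, "' first",
         call. = FALSE)
  p
}

#' Run one pipeline step
#'
#' Subcommands: \code{synth} (generate a synthetic study genome),
#' \code{extract} (promoter regions), \code{filter} (Set1),
#' \code{classify} (promoter classes), \code{scan} (PPS search),
#' \code{cluster} (class grouping), \code{profile} (conservation profiles),
#' \code{support} (U test from four counts in \code{extra}),
#' \code{export} (PPS database in TSV/BED/GFF3).
#'
#' @param step subcommand name.
#' @param config configuration list from [read_config()].
#' @param extra optional step-specific arguments (e.g. counts for
#'   \code{support}).
#' @return step-dependent result, invisibly; artefacts are written under
#'   \code{config$paths$workdir}.
#' @export
run_step <- function(step = c("synth", "extract", "filter", "classify",
                              "scan", "cluster", "profile", "support",
                              "export"),
                     config = read_config(), extra = list()) {
  step <- match.arg(step)
  cfg <- config
  dir.create(cfg$paths$workdir, showWarnings = FALSE, recursive = TRUE)
  switch(step,
    synth = {
      sp <- do.call(synth_spec, merge_config(list(seed = cfg$seed),
                                             cfg$synth))
      gen <- synth_generate(sp, dir = cfg$paths$workdir)
      message("synth: ", sum(nchar(gen$genome)), " nt, ",
              nrow(gen$genes), " genes, ", nrow(gen$truth), " planted rows")
      invisible(gen)
    },
    extract = {
      gpath <- cfg$paths$genome %||% need_artifact(cfg, "genome.fa", "synth")
      apath <- cfg$paths$genes %||% need_artifact(cfg, "genes.gff3", "synth")
      genome <- read_genome(gpath)
      genes <- read_genes(apath)
      proms <- extract_promoters(genome, genes)
      write_tsv_artifact(proms, art(cfg, "promoters.tsv"), cfg)
      dropped <- attr(proms, "dropped")
      if (nrow(dropped))
        write_tsv_artifact(dropped, art(cfg, "dropped_genes.tsv"), cfg)
      message("extract: ", nrow(proms), " regions (", nrow(dropped),
              " dropped)")
      invisible(proms)
    },
    filter = {
      proms <- read_tsv_artifact(need_artifact(cfg, "promoters.tsv",
                                               "extract"))
      res <- filter_promoters(proms, config_filter_params(cfg))
      write_tsv_artifact(res$kept, art(cfg, "set1.tsv"), cfg)
      write_tsv_artifact(res$report, art(cfg, "filter_report.tsv"), cfg)
      message("filter: kept ", nrow(res$kept), " of ", nrow(proms))
      invisible(res)
    },
    classify = {
      set1 <- read_tsv_artifact(need_artifact(cfg, "set1.tsv", "filter"))
      seqs <- setNames(set1$seq, set1$gene_id)
      ga <- do.call(ga_params, cfg$ga)
      cls <- build_classes(seqs, z_threshold = cfg$classify$z_threshold,
                           min_class_size = cfg$classify$min_class_size,
                           n_shuffles = cfg$classify$n_shuffles,
                           ga = ga, gaps = gap_params(cfg$scan$d),
                           seed = cfg$seed,
                           max_classes = cfg$classify$max_classes)
      cdir <- art(cfg, "classes")
      dir.create(cdir, showWarnings = FALSE)
      reg <- lapply(cls, function(cl) {
        prefix <- file.path(cdir, sprintf("class_%03d", cl$class_id))
        write_pwm(cl$pwm, prefix, class_id = cl$class_id, M = cl$M)
        writeLines(cl$members, paste0(prefix, "_members.txt"))
        list(class_id = cl$class_id, volume = cl$volume, L1 = cl$L1,
             prefix = basename(prefix))
      })
      jsonlite::write_json(list(seed = cfg$seed, classes = reg),
                           art(cfg, "class_registry.json"),
                           auto_unbox = TRUE, digits = NA)
      message("classify: ", length(cls), " classes accepted")
      invisible(cls)
    },
    scan = {
      need_artifact(cfg, "class_registry.json", "classify")
      gpath <- cfg$paths$genome %||% need_artifact(cfg, "genome.fa", "synth")
      genome <- read_genome(gpath)
      cls <- load_classes(cfg)
      res <- scan_genome(genome, cls, config_scan(cfg), seed = cfg$seed)
      export_pps(res$records[, .PPS_COLS], art(cfg, "pps.tsv"), "tsv",
                 header = provenance(cfg))
      write_null_cache(res$nulls, art(cfg, "nulls.json"))
      message("scan: ", nrow(res$records), " PPS records")
      invisible(res)
    },
    cluster = {
      need_artifact(cfg, "class_registry.json", "classify")
      cls <- load_classes(cfg)
      Ms <- setNames(lapply(cls, `[[`, "M"),
                     vapply(cls, function(c) as.character(c$class_id), ""))
      prm <- matrix_align_params(d = cfg$cluster$d, n_mix = cfg$cluster$n_mix,
                                 seed = cfg$seed)
      D <- class_distance_matrix(Ms, prm, squared = isTRUE(cfg$cluster$squared))
      grp <- complete_linkage(D, cut = cfg$cluster$cut)
      write_tsv_artifact(as.data.frame(D), art(cfg, "class_distances.tsv"),
                         cfg)
      write_tsv_artifact(grp$groups, art(cfg, "class_groups.tsv"), cfg)
      writeLines(grp$newick, art(cfg, "class_dendrogram.nwk"))
      message("cluster: ", length(unique(grp$groups$group)), " groups")
      invisible(grp)
    },
    profile = {
      cls <- load_classes(cfg)
      prof <- do.call(rbind, lapply(cls, function(cl)
        data.frame(class_id = cl$class_id, column = 2:(cl$L1),
                   X = conservation_profile(cl$pwm))))
      write_tsv_artifact(prof, art(cfg, "conservation_profiles.tsv"), cfg)
      invisible(prof)
    },
    support = {
      cnt <- extra
      res <- u_test(cnt$m1, cnt$n1, cnt$m2, cnt$n2,
                    alpha = cnt$alpha %||% 0.05)
      jsonlite::write_json(res, art(cfg, "support.json"), auto_unbox = TRUE,
                           digits = NA)
      message(sprintf("support: U = %.3f (critical %.3f): %s",
                      res$U, res$critical, res$decision))
      invisible(res)
    },
    export = {
      pps <- read_pps(need_artifact(cfg, "pps.tsv", "scan"))
      export_pps(pps, art(cfg, "pps.bed"), "bed", header = provenance(cfg))
      export_pps(pps, art(cfg, "pps.gff3"), "gff3", header = provenance(cfg))
      message("export: ", nrow(pps), " records -> BED + GFF3")
      invisible(pps)
    }
  )
}

# reload classes persisted by the classify step
load_classes <- function(cfg) {
  reg <- jsonlite::read_json(need_artifact(cfg, "class_registry.json",
                                           "classify"),
                             simplifyVector = TRUE)
  lapply(seq_len(nrow(reg$classes)), function(i) {
    prefix <- art(cfg, "classes", reg$classes$prefix[i])
    pwm <- read_pwm(prefix)
    Mdf <- read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                      header = TRUE, check.names = FALSE)
    M <- as.matrix(Mdf[, -1, drop = FALSE])
    rownames(M) <- Mdf[[1]]
    structure(list(class_id = reg$classes$class_id[i],
                   L1 = reg$classes$L1[i], M = M, pwm = pwm,
                   members = readLines(paste0(prefix, "_members.txt")),
                   volume = reg$classes$volume[i]),
              class = "promoter_class")
  })
}
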