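# Pipeline: QC -> diversity / ROH / inbreeding -> PCA / admixture ->
# per-group iHS -> candidate-gene annotation, from one config, with a
# persisted run manifest and stage-level resume.

pipelineDefaults <- function() list(
  genome_length_bp = 100100000,     # SNP-covered autosome span; override per assembly
  polarize_mode = "major_ancestral",
  qc = list(min_call_rate = 0.99, min_maf = 0.01, max_sample_missing = 0.10),
  roh = list(),                     # ROHParams() defaults
  pca = list(n_components = 5, scaling = "patterson"),
  admixture = list(enabled = TRUE, K_range = 2:5, folds = 3, seed_offset = 77),
  ihs = list(limit = 0.05, max_gap_bp = 200000, min_derived_freq = 0.05,
             window_bp = 1e6, step_bp = 5e5, top_fraction = 0.01,
             snp_threshold = 4.0, n_bins = 20, min_bin = 10)
)

mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Assemble a pipeline run configuration
#'
#' @param vcf genotype VCF (QC and all genotype-based stages).
#' @param popmap 2-column TSV sample_id/population.
#' @param outDir output directory (created if needed).
#' @param gtf optional Ensembl GTF for candidate-gene annotation.
#' @param phasedVcf phased VCF for the iHS scan (defaults to `vcf`).
#' @param groups named list of population-code vectors defining the scan
#'   groups (iHS is standardized within each group independently); default
#'   one group `all` holding every population.
#' @param seed integer seed.
#' @param ... overrides of the default stage parameters, e.g.
#'   `qc = list(min_maf = 0.05)`, `genome_length_bp = 5e7`,
#'   `admixture = list(K_range = 2:4)`.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(vcf, popmap, outDir, gtf = NULL, phasedVcf = NULL,
                      groups = NULL, seed = 1L, ...) {
  cfg <- mergeConfig(pipelineDefaults(), list(...))
  cfg$vcf <- vcf; cfg$popmap <- popmap; cfg$out_dir <- outDir
  cfg$gtf <- gtf
  cfg$phased_vcf <- if (is.null(phasedVcf)) vcf else phasedVcf
  cfg$groups <- groups
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file with the same fields as the `runConfig()`
#'   arguments (`vcf`, `popmap`, `out_dir`, optional `gtf`, `phased_vcf`,
#'   `groups`, `seed`, stage parameter blocks).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$vcf), !is.null(y$popmap), !is.null(y$out_dir))
  extra <- y[setdiff(names(y), c("vcf", "popmap", "out_dir", "gtf",
                                 "phased_vcf", "groups", "seed"))]
  do.call(runConfig, c(list(
    vcf = y$vcf, popmap = y$popmap, outDir = y$out_dir, gtf = y$gtf,
    phasedVcf = y$phased_vcf, groups = y$groups,
    seed = if (is.null(y$seed)) 1L else y$seed), extra))
}

paramsHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

fileChecksums <- function(paths) {
  ex <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ex] <- unname(tools::md5sum(paths[ex]))
  setNames(out, paths)
}

#' Run the full analysis pipeline
#'
#' Stage order: `qc`, `diversity`, `roh`, `inbreeding`, `pca`,
#' `admixture` (optional), one `ihs_<group>` stage per scan group, and
#' `annotate` (when a GTF is given). Every stage records its parameter
#' hash, input and output checksums in `<out_dir>/manifest.json`; on a
#' rerun a stage is skipped when its parameters and outputs are unchanged
#' and no upstream stage was recomputed, so deleting one stage's output
#' recomputes only that stage and its dependents. All output tables are
#' TSV with a commented parameter header. A stage failure aborts with the
#' stage name after persisting the manifest.
#'
#' @param cfg a [runConfig()] object (or a YAML path, see
#'   [readRunConfig()]).
#' @return the run manifest, invisibly (list: config hash, per-stage
#'   status/params/inputs/outputs).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(cfg$out_dir, "manifest.json")
  old <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else
    list(stages = NULL)
  manifest <- list(config_hash = paramsHash(unclass(cfg)), stages = list())

  pops <- readPopulationMap(cfg$popmap)
  groups <- cfg$groups
  if (is.null(groups))
    groups <- list(all = sort(unique(populations(pops))))
  for (gn in names(groups))
    if (!all(groups[[gn]] %in% populations(pops)))
      stop("group ", gn, " references unknown population(s): ",
           paste(setdiff(groups[[gn]], populations(pops)), collapse = ", "))

  state <- new.env()
  anyRecomputed <- new.env(); anyRecomputed$stages <- character()

  runStage <- function(name, deps, params, inputs, outputs, compute, load) {
    rec <- old$stages[[name]]
    ph <- paramsHash(params)
    upstreamDirty <- any(deps %in% anyRecomputed$stages)
    clean <- !is.null(rec) && identical(rec$status, "complete") &&
      identical(rec$params_hash, ph) && !upstreamDirty &&
      all(file.exists(outputs)) &&
      identical(unname(fileChecksums(outputs)), unname(unlist(rec$outputs)))
    stageRec <- list(params_hash = ph, inputs = as.list(fileChecksums(inputs)),
                     status = "failed", outputs = list())
    manifest$stages[[name]] <<- stageRec
    if (clean) {
      message("pipeline: stage ", name, " up to date; skipping")
      obj <- load()
    } else {
      message("pipeline: running stage ", name)
      obj <- tryCatch(compute(), error = function(e) {
        manifest$stages[[name]]$status <<- "failed"
        writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                                    digits = NA), manifestPath)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      anyRecomputed$stages <- c(anyRecomputed$stages, name)
    }
    manifest$stages[[name]]$status <<- "complete"
    manifest$stages[[name]]$outputs <<- as.list(fileChecksums(outputs))
    obj
  }

  op <- function(...) file.path(cfg$out_dir, paste0(...))

  # -- qc -------------------------------------------------------------
  qcOut <- c(op("qc_genotypes.vcf"), op("qc_report.tsv"))
  qc <- runStage("qc", character(), c(cfg$qc, seed = cfg$seed),
    inputs = cfg$vcf,
    outputs = qcOut,
    compute = function() {
      g <- readVCF(cfg$vcf)
      res <- filterGenotypes(g, cfg$qc$min_call_rate, cfg$qc$min_maf,
                             cfg$qc$max_sample_missing)
      writeVCF(res$genotypes, qcOut[1L])
      writeResultTSV(qcCounts(res$report), qcOut[2L],
                     params = as.list(qcThresholds(res$report)))
      res$genotypes
    },
    load = function() readVCF(qcOut[1L]))

  # -- diversity -------------------------------------------------------
  divOut <- op("diversity.tsv")
  runStage("diversity", "qc", list(), inputs = qcOut[1L], outputs = divOut,
    compute = function() {
      d <- diversityTable(qc, pops)
      writeResultTSV(d, divOut)
      d
    },
    load = function() NULL)

  # -- roh -------------------------------------------------------------
  rohParams <- do.call(ROHParams, cfg$roh)
  rohOut <- c(op("roh_segments.tsv"), op("roh_summary.tsv"))
  roh <- runStage("roh", "qc", cfg$roh, inputs = qcOut[1L], outputs = rohOut,
    compute = function() {
      segs <- detectROH(qc, rohParams)
      writeResultTSV(segs, rohOut[1L],
                     params = list(min_kb = rohParams@minKb,
                                   window_snp = rohParams@windowSnp))
      sm <- summarizeROH(segs, pops)
      writeResultTSV(cbind(data.frame(population = rownames(sm$class_counts)),
                           as.data.frame(sm$class_counts)), rohOut[2L])
      segs
    },
    load = function() {
      d <- read.table(rohOut[1L], header = TRUE, sep = "\t",
                      comment.char = "#")
      if (nrow(d)) d$class <- rohClass(d$length_bp)
      d
    })

  # -- inbreeding ------------------------------------------------------
  inbOut <- c(op("inbreeding_samples.tsv"), op("inbreeding_populations.tsv"))
  runStage("inbreeding", c("qc", "roh"),
           list(genome_length_bp = cfg$genome_length_bp),
    inputs = rohOut[1L], outputs = inbOut,
    compute = function() {
      tb <- inbreedingTable(qc, pops, roh, cfg$genome_length_bp)
      writeResultTSV(tb$per_sample, inbOut[1L],
                     params = list(genome_length_bp = cfg$genome_length_bp))
      writeResultTSV(tb$per_population, inbOut[2L])
      tb
    },
    load = function() NULL)

  # -- pca -------------------------------------------------------------
  pcaOut <- c(op("pca_coordinates.tsv"), op("pca_variance.tsv"))
  runStage("pca", "qc", cfg$pca, inputs = qcOut[1L], outputs = pcaOut,
    compute = function() {
      pr <- pcaGenotypes(qc, cfg$pca$n_components, cfg$pca$scaling)
      co <- data.frame(sample_id = sampleIDs(qc),
                       population = populations(pops)[sampleIDs(qc)],
                       pcaCoordinates(pr))
      writeResultTSV(co, pcaOut[1L], params = list(scaling = cfg$pca$scaling))
      writeResultTSV(data.frame(component = seq_along(explainedVariance(pr)),
                                explained_fraction = explainedVariance(pr)),
                     pcaOut[2L])
      pr
    },
    load = function() NULL)

  # -- admixture -------------------------------------------------------
  if (isTRUE(cfg$admixture$enabled)) {
    admOut <- c(op("admixture_cv.tsv"), op("admixture_Q.tsv"))
    runStage("admixture", "qc", cfg$admixture, inputs = qcOut[1L],
      outputs = admOut,
      compute = function() {
        KR <- cfg$admixture$K_range
        cv <- cvAdmixture(qc, KR, folds = cfg$admixture$folds,
                          seed = cfg$seed + cfg$admixture$seed_offset)
        writeResultTSV(cv, admOut[1L],
                       params = list(folds = cfg$admixture$folds,
                                     best_K = attr(cv, "best_K")))
        fit <- fitAdmixture(qc, attr(cv, "best_K"),
                            seed = cfg$seed + cfg$admixture$seed_offset)
        qd <- data.frame(sample_id = sampleIDs(qc),
                         population = populations(pops)[sampleIDs(qc)],
                         ancestryQ(fit))
        qd <- qd[order(qd$population), ]   # bar-plot order
        writeResultTSV(qd, admOut[2L], params = list(K = attr(cv, "best_K")))
        fit
      },
      load = function() NULL)
  }

  # -- per-group iHS ---------------------------------------------------
  keepKey <- paste(chromosomes(qc), positions(qc))
  scans <- list()
  for (gn in names(groups)) {
    nm <- paste0("ihs_", gn)
    outs <- c(op(nm, ".tsv"), op(nm, "_windows.tsv"), op(nm, "_regions.tsv"))
    scans[[gn]] <- runStage(nm, "qc",
      c(cfg$ihs, list(group = groups[[gn]],
                      polarize_mode = cfg$polarize_mode)),
      inputs = c(cfg$phased_vcf, qcOut[1L]), outputs = outs,
      compute = function() {
        h <- readVCF(cfg$phased_vcf, phasedRequired = TRUE)
        inGrp <- sampleIDs(h)[populations(pops)[sampleIDs(h)] %in%
                                groups[[gn]]]
        h <- h[inGrp, which(paste(chromosomes(h), positions(h)) %in% keepKey)]
        h <- polarize(h, cfg$polarize_mode)
        sc <- ihsScan(h, cfg$ihs$limit, cfg$ihs$max_gap_bp,
                      cfg$ihs$min_derived_freq)
        std <- standardizeIHS(sc, cfg$ihs$n_bins, cfg$ihs$min_bin)
        ws <- windowScan(std, cfg$ihs$window_bp, cfg$ihs$step_bp,
                         cfg$ihs$top_fraction, cfg$ihs$snp_threshold)
        writeResultTSV(std, outs[1L],
                       params = list(group = paste(groups[[gn]],
                                                   collapse = ","),
                                     polarize = cfg$polarize_mode))
        writeResultTSV(ws$windows, outs[2L],
                       params = list(threshold = ws$threshold))
        writeResultTSV(ws$regions, outs[3L])
        ws
      },
      load = function() {
        regions <- read.table(outs[3L], header = TRUE, sep = "\t",
                              comment.char = "#")
        list(regions = regions)
      })
  }

  # -- annotate --------------------------------------------------------
  if (!is.null(cfg$gtf)) {
    annOut <- op("candidate_genes.tsv")
    runStage("annotate", paste0("ihs_", names(groups)), list(),
      inputs = c(cfg$gtf,
                 file.path(cfg$out_dir,
                           paste0("ihs_", names(groups), "_regions.tsv"))),
      outputs = annOut,
      compute = function() {
        genes <- loadGTF(cfg$gtf)
        rows <- lapply(names(groups), function(gn) {
          hits <- intersectRegions(scans[[gn]]$regions, genes)$per_region
          if (nrow(hits)) cbind(group = gn, hits) else NULL
        })
        rows <- do.call(rbind, rows)
        if (is.null(rows))
          rows <- data.frame(group = character(), region_id = integer(),
                             chrom = character(), region_start = integer(),
                             region_end = integer(), gene_name = character(),
                             gene_id = character(), overlap_bp = integer())
        writeResultTSV(rows, annOut)
        rows
      },
      load = function() NULL)
  }

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                              digits = NA), manifestPath)
  invisible(manifest)
}
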