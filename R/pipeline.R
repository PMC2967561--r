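# End-to-end orchestration: filter -> negatives -> encode -> train ->
# evaluate -> scan, with every artifact written under one run directory and
# a manifest recording the seed, configuration and output checksums.

.defaultPipelineConfig <- function() {
  list(seed = 1L,
       outDir = "pdzscan_run",
       simulate = NULL,          # list(nDomains=..., ...) to use synthetic data
       input = NULL,             # list(interactions=path, proteome=path)
       filter = list(enabled = FALSE, minPeptides = 10L),
       negatives = list(method = "pwm_selected", ratio = 2,
                        redundancyMaxIdentity = 3L),
       encoding = "contact_map",
       contactMap = NULL,        # path; NULL = shipped default
       svm = list(gamma = 0.05, cost = 1, weighted = TRUE),
       evaluate = list(schemes = c("ten_fold"), folds = 10L, repeats = 10L),
       scan = list(nDomains = 1L))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full prediction pipeline
#'
#' Chains the package's stages in order -- data loading (or synthetic
#' simulation), genomic-likeness filtering of positive-only data, artificial
#' negative generation, feature encoding, weighted-cost SVM training,
#' cross-validation, and proteome scanning -- writing all artifacts under a
#' run directory together with a manifest (package version, seed, input
#' configuration, output checksums). No stage mutates its inputs; identical
#' seeds give identical artifacts.
#'
#' @param config a nested list or the path to a YAML file; unspecified
#'   entries fall back to documented defaults. Key entries: `seed`,
#'   `outDir`, either `simulate` (synthetic-data parameters) or `input`
#'   (paths to an interaction TSV and proteome FASTA), `filter`,
#'   `negatives`, `encoding`, `svm` (gamma, cost, weighted) and `evaluate`
#'   (schemes, folds, repeats).
#' @return invisibly, a list with the trained model, the evaluation results
#'   and the manifest.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- data -------------------------------------------------------------
  dataset <- stage("load", {
    if (!is.null(cfg$simulate)) {
      do.call(syntheticDataset,
              c(cfg$simulate[setdiff(names(cfg$simulate), "seed")],
                list(seed = cfg$seed)))
    } else if (!is.null(cfg$input)) {
      iset <- readInteractions(cfg$input$interactions)
      tails <- if (!is.null(cfg$input$proteome))
        extractCTerminalTails(cfg$input$proteome) else NULL
      list(interactions = iset, tails = tails)
    } else stop("config must provide either 'simulate' or 'input'")
  })
  iset <- dataset$interactions
  tails <- dataset$tails
  cmap <- if (is.null(cfg$contactMap)) defaultContactMap() else
    loadContactMap(cfg$contactMap)

  # -- filter + negatives (positive-only route) -------------------------
  training <- stage("negatives", {
    pos <- positiveOnlyView(iset)
    if (isTRUE(cfg$filter$enabled)) {
      if (is.null(tails)) stop("genomic filter requires a proteome")
      pos <- enrichGenomicLike(pos, tails,
                               minPeptides = cfg$filter$minPeptides)
      writeInteractions(pos, file.path(cfg$outDir, "filtered.tsv"))
    }
    tr <- addArtificialNegatives(pos,
                                 method = cfg$negatives$method,
                                 ratio = cfg$negatives$ratio,
                                 redundancyMaxIdentity =
                                   cfg$negatives$redundancyMaxIdentity,
                                 seed = cfg$seed + 1L,
                                 dropInsufficient = TRUE)
    writeInteractions(tr, file.path(cfg$outDir, "training.tsv"))
    tr
  })

  # -- train ------------------------------------------------------------
  model <- stage("train", {
    X <- encodeInteractions(training, method = cfg$encoding, cmap = cmap)
    y <- attr(X, "labels")
    if (isTRUE(cfg$svm$grid)) {
      gs <- gridSearch(X, y, cGrid = cfg$svm$cGrid %||% 2^seq(-5, 15, 2),
                       gammaGrid = cfg$svm$gammaGrid %||% 2^seq(-15, 3, 2),
                       folds = 5L, seed = cfg$seed + 2L,
                       weighted = cfg$svm$weighted)
      cfg$svm$cost <- unname(gs$best["C"])
      cfg$svm$gamma <- unname(gs$best["gamma"])
    }
    m <- trainSVM(X, y, gamma = cfg$svm$gamma, cost = cfg$svm$cost,
                  weighted = cfg$svm$weighted, encoding = cfg$encoding)
    writeSVMModel(m, file.path(cfg$outDir, "model.txt"))
    m
  })

  # -- evaluate ---------------------------------------------------------
  evals <- stage("evaluate", {
    res <- lapply(cfg$evaluate$schemes, function(s)
      runCV(training, gamma = cfg$svm$gamma, cost = cfg$svm$cost,
            scheme = s, encoding = cfg$encoding, cmap = cmap,
            folds = cfg$evaluate$folds, repeats = cfg$evaluate$repeats,
            seed = cfg$seed + 3L, weighted = cfg$svm$weighted))
    names(res) <- cfg$evaluate$schemes
    summ <- data.frame(scheme = cfg$evaluate$schemes,
                       meanRocAUC = vapply(res, `[[`, numeric(1), "meanRocAUC"),
                       meanPrAUC = vapply(res, `[[`, numeric(1), "meanPrAUC"))
    utils::write.table(summ, file.path(cfg$outDir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  # -- scan -------------------------------------------------------------
  scans <- stage("scan", {
    if (is.null(tails) || cfg$scan$nDomains < 1L) NULL else {
      dm <- training@domains
      n <- min(cfg$scan$nDomains, nrow(dm))
      out <- lapply(seq_len(n), function(i) {
        sr <- scanProteome(model, dm$binding_site[i], tails, cmap = cmap,
                           domainId = dm$id[i])
        writeScanResult(sr, file.path(cfg$outDir,
                                      paste0("scan_", dm$id[i], ".tsv")))
        sr
      })
      names(out) <- dm$id[seq_len(n)]
      out
    }
  })

  # -- manifest ---------------------------------------------------------
  files <- list.files(cfg$outDir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "pdzscan",
    version = as.character(utils::packageVersion("pdzscan")),
    seed = cfg$seed,
    config = cfg,
    checksums = as.list(tools::md5sum(sort(files))))
  names(manifest$checksums) <- basename(sort(files))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, evaluation = evals, scans = scans,
                 training = training, manifest = manifest))
}
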