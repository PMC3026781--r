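## Pipeline orchestration: run the stages simulate -> annotate -> discover
## -> edit -> profile -> stats -> clinical against a study directory, each
## stage reading its inputs from and writing its artifacts to that
## directory, with a structured record-count log.

.STAGES <- c("simulate", "annotate", "discover", "edit", "profile",
             "stats", "clinical")

.logCounts <- function(dir, stage, ...) {
    kv <- c(...)
    tab <- data.frame(stage = stage, key = names(kv),
                      value = unname(kv), stringsAsFactors = FALSE)
    path <- file.path(dir, "log.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(path),
                       append = file.exists(path))
    message("[", stage, "] ",
            paste(names(kv), unname(kv), sep = "=", collapse = " "))
}

.need <- function(dir, files, stage, producer) {
    missing <- files[!file.exists(file.path(dir, files))]
    if (length(missing))
        stop("stage '", stage, "' needs ", paste(missing, collapse = ", "),
             "; run stage '", producer, "' first")
}

#' Run the analysis pipeline on a study directory
#'
#' Executes the requested stages in the fixed order simulate, annotate,
#' discover, edit, profile, stats, clinical. The simulate stage writes a
#' full synthetic study into \code{outdir}; each later stage reads the
#' files it needs from \code{outdir} (so real data can be analysed by
#' placing equivalent files there) and writes its TSV artifacts next to
#' them. Stages are deterministic given identical inputs and
#' configuration; the resolved configuration is written beside the
#' outputs.
#'
#' @param outdir study directory
#' @param config a \code{\link{simConfig}} (also carries analysis seeds)
#' @param stages subset of stages to run (default: all)
#' @param markerThreshold normalized marker expression bound for the
#'   high-risk cluster flag
#' @param k flat cluster count for the sample clustering
#' @return invisibly, a named list of the artifacts produced
#' @export
runPipeline <- function(outdir, config = simConfig(),
                        stages = .STAGES, markerThreshold = 250, k = 3L) {
    stages <- match.arg(stages, .STAGES, several.ok = TRUE)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    ## fresh per-run log so identical runs give identical artifacts
    unlink(file.path(outdir, "log.tsv"))
    out <- list()
    tsv <- function(x, name) {
        utils::write.table(x, file.path(outdir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        name
    }

    if ("simulate" %in% stages) {
        truth <- generateReference(config)
        reads <- simulateReads(truth, config)
        clinical <- simulateClinical(truth, config)
        writeStudy(truth, reads, clinical, outdir)
        Biostrings::writeXStringSet(truth$dbs$miRNA,
            file.path(outdir, "db_miRNA.fa"))
        .logCounts(outdir, "simulate",
                   loci = length(truth$loci), reads = nrow(reads$reads),
                   samples = nrow(truth$samples))
        out$truth <- truth
    }

    if ("annotate" %in% stages) {
        .need(outdir, c("genome.fa", "samples.tsv"), "annotate", "simulate")
        readFiles <- list.files(file.path(outdir, "reads"),
                                pattern = "\\.fa$", full.names = TRUE)
        if (!length(readFiles))
            stop("stage 'annotate' needs reads/*.fa; run stage 'simulate' first")
        reads <- readReadsFasta(readFiles)
        dbs <- readDbs(outdir)
        genome <- Biostrings::readDNAStringSet(
            file.path(outdir, "genome.fa"))[[1L]]
        annot <- classifyReads(reads, dbs, genome = genome)
        tsv(annot, "annotations.tsv")
        expr <- countAndNormalize(annot)
        tsv(data.frame(mirna = rownames(expr$counts), expr$counts,
                       check.names = FALSE), "expression_counts.tsv")
        tsv(data.frame(mirna = rownames(expr$normalized), expr$normalized,
                       check.names = FALSE), "expression_normalized.tsv")
        tsv(data.frame(sample = rownames(expr$composition),
                       expr$composition, check.names = FALSE),
            "composition.tsv")
        .logCounts(outdir, "annotate", reads = sum(annot$count),
                   miRNA = sum(annot$count[annot$db_class == "miRNA"]),
                   genome = sum(annot$count[annot$db_class == "genome"]),
                   unmatched = sum(annot$count[annot$db_class == "unmatched"]))
        out$annot <- annot
        out$expr <- expr
    }

    if ("discover" %in% stages) {
        .need(outdir, c("annotations.tsv", "loci.tsv", "genome.fa",
                        "conservation.tsv"), "discover", "annotate")
        annot <- utils::read.table(file.path(outdir, "annotations.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
        loci <- readLoci(file.path(outdir, "loci.tsv"))
        genome <- Biostrings::readDNAStringSet(
            file.path(outdir, "genome.fa"))[[1L]]
        track <- readConservation(file.path(outdir, "conservation.tsv"))
        calls <- discoverNovel(annot, loci, genome, track = track)
        tsv(calls, "candidates.tsv")
        if (nrow(calls)) {
            bed <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                              end = calls$end, name = calls$group_id,
                              score = calls$support, strand = calls$strand)
            utils::write.table(bed, file.path(outdir, "candidates.bed"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
            nov <- calls[calls$class == "novel", ]
            if (nrow(nov)) {
                ss <- Biostrings::DNAStringSet(nov$rep_seq)
                names(ss) <- sprintf("%s class=novel count=%d",
                                     nov$group_id, nov$support)
                Biostrings::writeXStringSet(ss,
                    file.path(outdir, "novel.fa"))
            }
        }
        .logCounts(outdir, "discover", candidates = nrow(calls),
                   novel = sum(calls$class == "novel"),
                   opposite = sum(calls$class == "opposite"),
                   antisense = sum(calls$class == "antisense"),
                   rejected = sum(calls$class == "rejected"))
        out$calls <- calls
    }

    needGroups <- function() {
        s <- utils::read.table(file.path(outdir, "samples.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
        stats::setNames(s$group, s$sample_id)
    }
    needAnnot <- function()
        utils::read.table(file.path(outdir, "annotations.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    needMature <- function() {
        db <- Biostrings::readDNAStringSet(file.path(outdir, "db_miRNA.fa"))
        db[!grepl("-pre$", names(db))]
    }

    if ("edit" %in% stages) {
        .need(outdir, c("annotations.tsv", "db_miRNA.fa", "samples.tsv"),
              "edit", "annotate")
        annot <- needAnnot()
        groups <- needGroups()
        matureSeqs <- needMature()
        mat <- annot[annot$db_class == "miRNA" & !annot$precursor_only, ]
        mat$group <- groups[mat$sample]
        profs <- lapply(names(matureSeqs), function(id) {
            sub <- mat[mat$ref_id == id, c("seq", "count", "group")]
            if (!nrow(sub)) return(NULL)
            modificationProfile(sub, as.character(matureSeqs[[id]]),
                                mirna = id)$sites
        })
        sites <- do.call(rbind, profs[!vapply(profs, is.null, logical(1))])
        if (is.null(sites)) sites <- data.frame()
        tsv(sites, "modification_sites.tsv")
        .logCounts(outdir, "edit",
                   sites = length(unique(paste(sites$mirna, sites$pos,
                                               sites$to))))
        out$sites <- sites
    }

    if ("profile" %in% stages) {
        .need(outdir, c("annotations.tsv", "db_miRNA.fa"), "profile",
              "annotate")
        se <- splitExpressionForms(needAnnot(), needMature())
        forms <- SummarizedExperiment::rowData(se)
        tsv(data.frame(mirna = forms$mirna, form = forms$form,
                       SummarizedExperiment::assay(se, "normalized"),
                       check.names = FALSE), "expression_forms.tsv")
        .logCounts(outdir, "profile", rows = nrow(se))
        out$forms <- se
    }

    if ("stats" %in% stages) {
        .need(outdir, c("expression_normalized.tsv", "samples.tsv"),
              "stats", "annotate")
        tab <- utils::read.table(file.path(outdir,
                                           "expression_normalized.tsv"),
                                 header = TRUE, sep = "\t",
                                 check.names = FALSE)
        normalized <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(normalized) <- tab$mirna
        groups <- needGroups()
        s <- utils::read.table(file.path(outdir, "samples.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
        filtered <- prevalenceFilter(normalized)
        marker <- .mirId(1L)
        cl <- clusterSamples(filtered, k = k,
                             groups = groups[colnames(filtered)],
                             marker = marker,
                             markerThreshold = markerThreshold)
        tsv(data.frame(sample = colnames(filtered), cluster = cl$labels,
                       highrisk = cl$labels %in% which(cl$highRisk)),
            "clusters.tsv")
        tsv(with(cl$hclust, data.frame(merge1 = merge[, 1L],
                                       merge2 = merge[, 2L],
                                       height = height)), "linkage.tsv")
        pairIds <- stats::setNames(s$pair_id, s$sample_id)
        paired <- colnames(filtered)[groups[colnames(filtered)] %in%
                                     c("HCC", "ANL")]
        sam <- samTest(filtered[, paired, drop = FALSE],
                       groups[paired], nPerm = 500L,
                       seed = config$seed + 3L)
        tsv(data.frame(mirna = names(sam$d), d = sam$d,
                       significant = names(sam$d) %in% sam$significant),
            "sam.tsv")
        tt <- pairedTTest(filtered[, paired, drop = FALSE],
                          groups[paired], pairIds[paired])
        tsv(tt, "ttest.tsv")
        .logCounts(outdir, "stats", filtered = nrow(filtered),
                   sam_significant = length(sam$significant),
                   highrisk_samples = length(cl$highRiskSamples))
        out$cluster <- cl
        out$sam <- sam
        out$ttest <- tt
    }

    if ("clinical" %in% stages) {
        .need(outdir, c("clinical.tsv", "clusters.tsv",
                        "expression_normalized.tsv", "samples.tsv"),
              "clinical", "stats")
        clin <- utils::read.table(file.path(outdir, "clinical.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
        clusters <- utils::read.table(file.path(outdir, "clusters.tsv"),
                                      header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
        tab <- utils::read.table(file.path(outdir,
                                           "expression_normalized.tsv"),
                                 header = TRUE, sep = "\t",
                                 check.names = FALSE)
        normalized <- as.matrix(tab[, -1L, drop = FALSE])
        rownames(normalized) <- tab$mirna
        groups <- needGroups()

        marker <- .mirId(1L)
        lab <- groups[colnames(normalized)] == "HCC"
        roc <- rocTable(normalized[marker, ], lab, direction = "high")
        tsv(roc$table, "roc_marker.tsv")

        hr <- stats::setNames(clusters$highrisk, clusters$sample)
        clin$highrisk <- as.integer(hr[clin$sample_id])
        km <- kmFit(clin$time_months, clin$event,
                    ifelse(clin$highrisk == 1L, "high-risk", "other"))
        tsv(km$curves, "km_curves.tsv")
        lr <- if (length(unique(clin$highrisk)) > 1L)
            logrankTest(clin$time_months, clin$event, clin$highrisk)
        else list(chisq = NA, df = NA, p = NA, flagged = TRUE)
        covs <- clin[grep("^path", names(clin))]
        covs$highrisk <- clin$highrisk
        constant <- vapply(covs, function(x) length(unique(x)) < 2L,
                           logical(1))
        if (any(constant))
            message("dropping constant covariate(s): ",
                    paste(names(covs)[constant], collapse = ", "))
        covs <- covs[!constant]
        cox <- NULL
        if (length(covs)) {
            ## small studies can separate perfectly; report and move on
            cox <- tryCatch(coxFit(covs, clin$time_months, clin$event),
                            error = function(e) {
                                message("Cox fit skipped: ",
                                        conditionMessage(e))
                                NULL
                            })
            if (!is.null(cox))
                tsv(cox$coefficients, "cox_summary.tsv")
        }
        tsv(data.frame(auc = roc$auc, logrank_chisq = lr$chisq,
                       logrank_p = lr$p), "clinical_summary.tsv")
        .logCounts(outdir, "clinical", patients = nrow(clin),
                   events = sum(clin$event))
        out$roc <- roc
        out$km <- km
        out$logrank <- lr
        out$cox <- cox
    }

    invisible(out)
}
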