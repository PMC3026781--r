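## Plain-text interchange: FASTA via Biostrings, BED via rtracklayer-free
## 6-column writer (0-based half-open, strand-aware), TSV tables, YAML
## config.

#' Write the synthetic study to a directory
#'
#' Writes genome and database FASTAs, the conservation track TSV
#' (0-based position, score), a 6-column BED of truth loci (0-based
#' half-open) plus a full locus TSV, the sample sheet, per-sample read
#' FASTAs (headers carry \code{sample=<id> count=<n>}; identical sequences
#' within a sample are collapsed), the clinical TSV, and the resolved
#' configuration YAML.
#'
#' @param truth a \code{SimTruth} from \code{\link{generateReference}}
#' @param reads result of \code{\link{simulateReads}} (optional)
#' @param clinical result of \code{\link{simulateClinical}} (optional)
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
writeStudy <- function(truth, reads = NULL, clinical = NULL, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    g <- Biostrings::DNAStringSet(truth$genome)
    names(g) <- "chrS"
    Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
    for (cls in names(truth$dbs))
        Biostrings::writeXStringSet(truth$dbs[[cls]],
                                    file.path(dir, paste0("db_", cls, ".fa")))
    cons <- data.frame(pos = seq_along(truth$conservation) - 1L,
                       score = round(truth$conservation, 6))
    utils::write.table(cons, file.path(dir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    loci <- truth$loci
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                      start = GenomicRanges::start(loci) - 1L,
                      end = GenomicRanges::end(loci),
                      name = loci$id, score = 0L,
                      strand = as.character(GenomicRanges::strand(loci)))
    utils::write.table(bed, file.path(dir, "loci.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    lt <- cbind(bed, class = loci$class, mirna = loci$mirna,
                mature_start = loci$mature_start - 1L,
                mature_end = loci$mature_end)
    utils::write.table(lt, file.path(dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth$samples, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reads)) {
        rdir <- file.path(dir, "reads")
        dir.create(rdir, showWarnings = FALSE)
        for (sid in unique(reads$reads$sample)) {
            sub <- reads$reads[reads$reads$sample == sid, ]
            tab <- stats::aggregate(count ~ seq, data = sub, FUN = sum)
            tab <- tab[order(tab$seq), ]
            ss <- Biostrings::DNAStringSet(tab$seq)
            names(ss) <- sprintf("%s_u%05d sample=%s count=%d", sid,
                                 seq_len(nrow(tab)), sid, tab$count)
            Biostrings::writeXStringSet(ss,
                file.path(rdir, paste0(sid, ".fa")))
        }
    }
    if (!is.null(clinical))
        utils::write.table(clinical, file.path(dir, "clinical.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    writeSimConfig(truth$config, file.path(dir, "config.yaml"))
    invisible(dir)
}

#' Write / read a SimConfig as YAML
#'
#' @param cfg a \code{\link{simConfig}}
#' @param path YAML file path
#' @return \code{readSimConfig} returns the reconstructed \code{SimConfig}
#' @export
writeSimConfig <- function(cfg, path) {
    x <- unclass(cfg)
    x$editing_spec <- as.list(cfg$editing_spec)
    x$fold_change_spec <- as.list(cfg$fold_change_spec)
    x$trim3_probs <- as.list(cfg$trim3_probs)
    x$class_mix <- as.list(cfg$class_mix)
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    x <- yaml::read_yaml(path)
    x$editing_spec <- as.data.frame(x$editing_spec,
                                    stringsAsFactors = FALSE)
    x$fold_change_spec <- as.data.frame(x$fold_change_spec,
                                        stringsAsFactors = FALSE)
    x$trim3_probs <- unlist(x$trim3_probs)
    x$class_mix <- unlist(x$class_mix)
    do.call(simConfig, x)
}

#' Read clone-read FASTAs into a read table
#'
#' Headers of the form \code{"<id> sample=<s> count=<n>"} are parsed into
#' sample ids and clone multiplicities; absent attributes default to the
#' file base name and count 1.
#'
#' @param files FASTA file paths
#' @return data.frame: read_id, sample, seq, count
#' @export
readReadsFasta <- function(files) {
    out <- lapply(files, function(f) {
        ss <- Biostrings::readDNAStringSet(f)
        hdr <- names(ss)
        id <- sub("\\s.*$", "", hdr)
        sample <- ifelse(grepl("sample=", hdr),
                         sub(".*sample=(\\S+).*", "\\1", hdr),
                         sub("\\.fa(sta)?$", "", basename(f)))
        count <- ifelse(grepl("count=", hdr),
                        as.integer(sub(".*count=(\\d+).*", "\\1", hdr)), 1L)
        data.frame(read_id = id, sample = sample,
                   seq = as.character(ss), count = count,
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, out)
}

#' Read reference databases from a study directory
#'
#' @param dir directory holding \code{db_<class>.fa} files
#' @return named list of \code{DNAStringSet} keyed by class
#' @export
readDbs <- function(dir) {
    files <- list.files(dir, pattern = "^db_.*\\.fa$", full.names = TRUE)
    if (!length(files)) stop("no db_<class>.fa files found in ", dir)
    dbs <- lapply(files, Biostrings::readDNAStringSet)
    names(dbs) <- sub("^db_(.*)\\.fa$", "\\1", basename(files))
    dbs
}

#' Read a conservation track TSV (0-based pos, score)
#'
#' @param path TSV file
#' @return numeric vector indexed by 1-based genomic position
#' @export
readConservation <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    out <- numeric(max(tab$pos) + 1L)
    out[tab$pos + 1L] <- tab$score
    out
}

#' Read the truth locus TSV as a GRanges
#'
#' @param path loci.tsv written by \code{\link{writeStudy}}
#' @return GRanges with id, class, mirna and mature span metadata
#' @export
readLoci <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    GenomicRanges::GRanges(tab$chrom,
                           IRanges::IRanges(tab$start + 1L, tab$end),
                           strand = tab$strand, id = tab$name,
                           class = tab$class, mirna = tab$mirna,
                           mature_start = tab$mature_start + 1L,
                           mature_end = tab$mature_end)
}
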