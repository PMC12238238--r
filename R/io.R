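# On-disk formats: FASTA, GFF3, FASTQ (Phred+33, fixed quality), TSV tables
# with provenance headers, and the YAML run configuration.

#' Read a protein FASTA file
#' @param path file path.
#' @return named `AAStringSet`.
#' @export
readProteinFasta <- function(path) Biostrings::readAAStringSet(path)

#' Read a nucleotide FASTA file
#' @param path file path.
#' @return named `DNAStringSet`.
#' @export
readNucleotideFasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param x `AAStringSet`/`DNAStringSet` or named character vector.
#' @param path output path.
#' @param type "AA" or "DNA" when `x` is a character vector.
#' @export
writeFasta <- function(x, path, type = c("AA", "DNA")) {
    if (is.character(x)) {
        type <- match.arg(type)
        x <- if (type == "AA") Biostrings::AAStringSet(x)
             else Biostrings::DNAStringSet(x)
    }
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

# light structural validation so malformed records fail with a line number
.checkGff3Lines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf != 9L]
    if (length(bad))
        stop("malformed GFF3 record at line ", bad[1], " of ", path,
             " (expected 9 tab-separated fields)", call. = FALSE)
    invisible(TRUE)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' CDS features (1-based, inclusive coordinates) with an `ID` attribute are
#' taken as genes; protein sequences are read from a companion protein FASTA
#' keyed by gene id.
#'
#' @param fastaPath nucleotide FASTA of contigs.
#' @param gffPath GFF3 annotation.
#' @param proteinPath protein FASTA named by gene id.
#' @param genomeId identifier for the genome (defaults to the FASTA stem).
#' @return an [AnnotatedGenome].
#' @export
readAnnotatedGenome <- function(fastaPath, gffPath, proteinPath,
                                genomeId = NULL) {
    contigs <- Biostrings::readDNAStringSet(fastaPath)
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    .checkGff3Lines(gffPath)
    gr <- rtracklayer::import(gffPath, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    prot <- Biostrings::readAAStringSet(proteinPath)
    ids <- gr$ID
    if (is.null(ids)) stop("GFF3 CDS features must carry an ID attribute")
    missing <- setdiff(ids, names(prot))
    if (length(missing))
        stop("no protein sequence for gene(s): ",
             paste(utils::head(missing, 3), collapse = ", "))
    out <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(gr)),
        ranges = IRanges::IRanges(GenomicRanges::start(gr),
                                  GenomicRanges::end(gr)),
        strand = GenomicRanges::strand(gr),
        gene_id = ids,
        protein = unname(as.character(prot[ids])))
    AnnotatedGenome(genomeId %||% sub("\\.(fa|fasta|fna)$", "",
                                      basename(fastaPath)),
                    contigs, out)
}

#' Write an annotated genome to FASTA + GFF3 (+ protein FASTA)
#' @param genome an [AnnotatedGenome].
#' @param dir output directory.
#' @return invisibly, the three file paths.
#' @export
writeAnnotatedGenome <- function(genome, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gid <- genomeId(genome)
    fa <- file.path(dir, paste0(gid, ".fna"))
    gff <- file.path(dir, paste0(gid, ".gff3"))
    faa <- file.path(dir, paste0(gid, ".faa"))
    Biostrings::writeXStringSet(contigs(genome), fa)
    g <- genes(genome)
    lines <- c("##gff-version 3",
               sprintf("%s\tSteroScreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g), GenomicRanges::end(g),
                       as.character(GenomicRanges::strand(g)),
                       S4Vectors::mcols(g)$gene_id))
    writeLines(lines, gff)
    writeFasta(proteins(genome), faa)
    invisible(c(fa, gff, faa))
}

#' Read FASTQ sequences
#' @param path FASTQ file.
#' @return character vector of read sequences (names = read ids).
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33, fixed quality "I")
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param idPrefix read id prefix.
#' @export
writeFastq <- function(reads, path, idPrefix = "read") {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
    lines <- as.vector(rbind(sprintf("@%s_%d", idPrefix, seq_along(reads)),
                             reads, "+", qual))
    writeLines(lines, path)
    invisible(path)
}

#' Write a results table with a provenance header
#'
#' Every pipeline stage table starts with a comment line carrying the
#' configuration fingerprint and seed, so results can be traced back to the
#' exact run that produced them.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config the run configuration list (fingerprinted).
#' @param seed the run seed.
#' @export
writeStageTable <- function(df, path, config = NULL, seed = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(config))
        writeLines(sprintf("# config=%s seed=%s",
                           configFingerprint(config),
                           format(seed %||% NA)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a stage/metadata TSV (provenance comments ignored)
#' @param path file path.
#' @export
readStageTable <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- synthetic-data writers ------------------------------------------------

#' Write a simulated pangenome to disk
#' @param sim result of [simulatePangenome()].
#' @param dir output directory.
#' @export
writePangenome <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (gid in names(sim$proteomes)) {
        if (!is.null(sim$genomes))
            writeAnnotatedGenome(sim$genomes[[gid]], dir)
        else
            writeFasta(sim$proteomes[[gid]],
                       file.path(dir, paste0(gid, ".faa")))
    }
    phen <- data.frame(genome = names(sim$phenotype),
                       phenotype = unname(sim$phenotype))
    utils::write.table(phen, file.path(dir, "phenotype.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(dir, "family_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$members, file.path(dir, "family_members.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$labels, file.path(dir, "gene_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Write a simulated metagenome cohort to disk
#' @param sim result of [simulateMetagenome()] with `output = "reads"`.
#' @param dir output directory.
#' @export
writeMetagenome <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim$reads))
        for (run in names(sim$reads))
            writeFastq(sim$reads[[run]],
                       file.path(dir, paste0(run, ".fastq")), idPrefix = run)
    utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(dir, "carriage_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeFasta(sim$panel, file.path(dir, "gene_panel.fna"), type = "DNA")
    writeFasta(sim$background, file.path(dir, "background.fna"), type = "DNA")
    invisible(dir)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All stage parameters with their defaults. Thresholds mirror the published
#' analysis where one exists (orthogroup screen, 95% gap-column trimming,
#' 500/450-residue length minima, CPM presence threshold of 1, one-million
#' read QC floor); tool-calibration-bound values (alignment bit floor,
#' E-value ceilings) are package defaults documented in the methods vignette.
#'
#' @return nested named list of configuration values.
#' @export
defaultConfig <- function() {
    list(
        seed = 1L,
        screen = list(min_bits = 50, gap_open = 11, gap_extend = 1,
                      target_label = "OYE"),
        profile = list(pseudocount = 1, match_occupancy = 0.5,
                       max_gap_frac = 0.95, min_len = 500L,
                       evalue_ceiling = 1e-3, null_n = 500L),
        context = list(window_genes = 8L, window_bp = 10000L),
        tree = list(max_distance = 5),
        metaprofile = list(k = 21L, theta = 0.3, cpm_threshold = 1,
                           qc_min_reads = 1e6, correct = TRUE,
                           drop_zero_cpm = FALSE))
}

.checkConfigRanges <- function(config) {
    ck <- function(cond, what)
        if (!cond) stop("configuration value out of range: ", what,
                        call. = FALSE)
    ck(config$screen$min_bits >= 0, "screen$min_bits >= 0")
    ck(config$profile$max_gap_frac >= 0 && config$profile$max_gap_frac <= 1,
       "profile$max_gap_frac in [0,1]")
    ck(config$profile$match_occupancy > 0 &&
       config$profile$match_occupancy <= 1,
       "profile$match_occupancy in (0,1]")
    ck(config$profile$null_n >= 200, "profile$null_n >= 200")
    ck(config$metaprofile$theta > 0 && config$metaprofile$theta <= 1,
       "metaprofile$theta in (0,1]")
    ck(config$metaprofile$cpm_threshold >= 0,
       "metaprofile$cpm_threshold >= 0")
    ck(config$metaprofile$qc_min_reads >= 0,
       "metaprofile$qc_min_reads >= 0")
    ck(config$context$window_genes >= 0, "context$window_genes >= 0")
    ck(config$context$window_bp >= 0, "context$window_bp >= 0")
    invisible(config)
}

#' Read and validate a run configuration
#'
#' YAML values are merged over [defaultConfig()]; unknown keys are rejected
#' and every threshold is checked against its documented domain.
#'
#' @param path YAML file, or a named list already in memory.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
    user <- if (is.list(path)) path else yaml::read_yaml(path)
    def <- defaultConfig()
    known_top <- c(names(def), "inputs", "output_dir", "simulate")
    unknown <- setdiff(names(user), known_top)
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    for (sec in intersect(names(user), names(def))) {
        if (is.list(def[[sec]])) {
            bad <- setdiff(names(user[[sec]]), names(def[[sec]]))
            if (length(bad))
                stop("unknown configuration key(s) in '", sec, "': ",
                     paste(bad, collapse = ", "), call. = FALSE)
            def[[sec]][names(user[[sec]])] <- user[[sec]]
        } else def[[sec]] <- user[[sec]]
    }
    def$inputs <- user$inputs
    def$output_dir <- user$output_dir
    def$simulate <- user$simulate
    .checkConfigRanges(def)
}
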