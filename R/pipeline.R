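## End-to-end pipeline driver and run configuration.
##
## Stages: preprocess (collapse / pair-merge) -> align or parse SAM ->
## junction calling -> pseudo-circular quantification -> downstream
## metrics -> outputs (BED6+, TSVs, FASTA, JSON manifest).

#' Assemble a pipeline run configuration
#'
#' Wraps [caller_config()] with file paths and run options; round-trips
#' losslessly through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param genome path to the reference genome FASTA.
#' @param fastq1,fastq2 read files (FASTQ, optionally gzipped); `fastq2`
#'   only for paired-end data.
#' @param sam optional pre-computed SAM from an external split-read
#'   aligner; when absent the bundled exact aligner is used (error-free
#'   synthetic data only).
#' @param gtf optional gene annotation (GTF) for exon-aware monomers and
#'   host-gene assignment.
#' @param model_file optional trained splice model JSON
#'   (see [write_splice_model()]); when absent a self-contained synthetic
#'   model is trained ([default_splice_model()]).
#' @param mirna_fasta optional miRNA FASTA for cleavage-site counting.
#' @param out_dir output directory.
#' @param seed seed recorded in the manifest and used for any stochastic
#'   step.
#' @param ... caller parameters forwarded to [caller_config()].
#' @return named list of class `run_config`.
#' @export
run_config <- function(genome, fastq1, fastq2 = NULL, sam = NULL, gtf = NULL,
                       model_file = NULL, mirna_fasta = NULL,
                       out_dir = "circpipe_out", seed = 1L, ...) {
  cfg <- list(genome = genome, fastq1 = fastq1, fastq2 = fastq2, sam = sam,
              gtf = gtf, model_file = model_file, mirna_fasta = mirna_fasta,
              out_dir = out_dir, seed = as.integer(seed),
              caller = caller_config(...))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path)
  x$caller <- do.call(caller_config, x$caller)
  x$seed <- as.integer(x$seed)
  for (f in c("fastq2", "sam", "gtf", "model_file", "mirna_fasta")) {
    if (is.null(x[[f]])) x[f] <- list(NULL)
  }
  class(x) <- "run_config"
  x
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full circRNA pipeline
#'
#' Executes preprocess, alignment/parsing, junction calling,
#' pseudo-circular quantification and downstream annotation, and writes
#' all outputs plus a JSON manifest of parameters, versions and input
#' checksums to the configured output directory.
#'
#' @param config a [run_config()].
#' @return list with `circs` (annotated quantified calls), `fusions`,
#'   `fusion_circs`, `refs`, `paths` of written outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$caller
  for (f in c("genome", "fastq1", "fastq2", "sam", "gtf", "model_file",
              "mirna_fasta")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("pipeline input '%s' not found: %s", f, p))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- pipeline_stage("genome", Biostrings::readDNAStringSet(config$genome))
  names(genome) <- sub("[ \t].*$", "", names(genome))
  annotation <- if (!is.null(config$gtf)) {
    pipeline_stage("annotation", read_gtf(config$gtf))
  } else NULL
  model <- if (!is.null(config$model_file)) {
    pipeline_stage("model", read_splice_model(config$model_file))
  } else default_splice_model()

  reads <- pipeline_stage("preprocess", prepare_reads(
    config$fastq1, config$fastq2,
    min_overlap = cfg$min_overlap, max_mismatch_frac = cfg$max_mismatch_frac))

  segs <- pipeline_stage("align", {
    if (!is.null(config$sam)) {
      parse_sam_segments(config$sam)
    } else {
      sam_lines <- naive_align_chimeric(reads, genome)
      writeLines(sam_lines, file.path(config$out_dir, "alignments.sam"))
      parse_sam_segments(sam_lines)
    }
  })
  pools <- split_chimeric(segs)

  called <- pipeline_stage("call", call_junctions(
    pools$chimeric, reads, genome, model, cfg))

  refs <- pipeline_stage("quantify-refs", build_pseudo_reference(
    called$circs, genome, annotation))
  quant <- pipeline_stage("quantify", quantify(refs, reads,
                                               min_overhang = cfg$min_overhang))
  circs <- called$circs
  circs$abundance <- unname(quant$abundance[circs$circ_id])

  mirnas <- if (!is.null(config$mirna_fasta)) {
    x <- Biostrings::readRNAStringSet(config$mirna_fasta)
    stats::setNames(chartr("U", "T", as.character(x)), names(x))
  } else NULL
  ## gene-level abundance from the linear read pool (reads per gene)
  gene_ab <- NULL
  if (!is.null(annotation) && nrow(pools$linear) > 0) {
    w <- stats::setNames(reads$count * reads$pair_weight, reads$read_id)
    lin <- pools$linear
    gene_of <- vapply(seq_len(nrow(lin)), function(i) {
      ex <- annotation[annotation$chrom == lin$chrom[i] &
                         annotation$start < lin$ref_end[i] &
                         annotation$end > lin$ref_start[i], , drop = FALSE]
      if (nrow(ex) == 0) NA_character_ else ex$gene_id[1]
    }, "")
    ok <- !is.na(gene_of)
    gene_ab <- tapply(unname(w[lin$read_id[ok]]), gene_of[ok], sum)
    gene_ab <- stats::setNames(as.numeric(gene_ab), names(gene_ab))
  }
  circs <- pipeline_stage("downstream", annotate_downstream(
    circs, refs, annotation, gene_ab, mirnas))

  fusion_circs <- pair_fusion_circs(called$fusions,
                                    max_span = cfg$fusion_max_span)

  paths <- list(
    circ_bed = file.path(config$out_dir, "circs.bed"),
    circ_tsv = file.path(config$out_dir, "circs.tsv"),
    fusion_junctions = file.path(config$out_dir, "fusion_junctions.tsv"),
    fusion_circs = file.path(config$out_dir, "fusion_circs.tsv"),
    pseudo_fa = file.path(config$out_dir, "pseudo_circular.fa"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  pipeline_stage("output", {
    write_circ_bed(circs, paths$circ_bed)
    write_abundance_tsv(circs, paths$circ_tsv)
    write_fusion_tsv(called$fusions, paths$fusion_junctions)
    write_fusion_tsv(fusion_circs, paths$fusion_circs)
    write_pseudo_fasta(refs, paths$pseudo_fa)
    inputs <- Filter(Negate(is.null),
                     config[c("genome", "fastq1", "fastq2", "sam", "gtf",
                              "model_file", "mirna_fasta")])
    manifest <- list(
      package = "circpipe",
      version = as.character(utils::packageVersion("circpipe")),
      seed = config$seed,
      parameters = cfg,
      inputs = lapply(inputs, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      }),
      n_collapsed_reads = nrow(reads),
      n_ambiguous_calls = called$n_ambiguous,
      unassigned_quant_weight = quant$n_ambiguous
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(list(circs = circs, fusions = called$fusions,
                 fusion_circs = fusion_circs, refs = refs, reads = reads,
                 paths = paths))
}
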