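# End-to-end pipeline driver: pairs -> regions -> CNV cross-reference
# (-> optional breakpoints / clustering / hotspots), with versioned
# provenance in every output file. Configuration is a JSON file or an R
# list mirroring the CLI flags.

#' Read a pipeline configuration
#'
#' JSON object with entries `rmsk`, `genome` (required paths), optional
#' `segdups`, `cnvs`, `out_dir`, and a `params` object overriding any of
#' the screening defaults (`min_length`, `min_sep`, `max_sep`,
#' `min_identity`, `min_aln_length`, `max_join_gap`, `same_family_only`).
#'
#' @param path JSON path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config not found: %s", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

default_params <- function() {
  list(min_length = 4000, min_sep = 10000, max_sep = 10000000,
       min_identity = 0.94, min_aln_length = 2000, max_join_gap = 5000,
       same_family_only = FALSE)
}

provenance_header <- function(stage, params, inputs) {
  checksums <- vapply(inputs, function(p) {
    if (is.null(p) || !file.exists(p)) NA_character_
    else unname(tools::md5sum(p))
  }, character(1))
  c(sprintf("# hervnahr %s v%s", stage,
            as.character(packageVersion("hervnahr"))),
    sprintf("# params: %s",
            paste(names(params), unlist(params), sep = "=",
                  collapse = " ")),
    sprintf("# input %s md5=%s", names(checksums), checksums))
}

write_tsv_with_header <- function(df, path, header_lines) {
  writeLines(c(header_lines, paste0("#", paste(names(df), collapse = "\t"))),
             path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Run the prediction pipeline
#'
#' Executes element joining and pair prediction, region condensation, and
#' (when a CNV table is configured) the CNV cross-reference. Every output
#' table carries a header recording the package version, parameters and
#' input checksums; reruns with an identical configuration are
#' byte-identical.
#'
#' @param config Configuration list (see [read_pipeline_config()]) or a
#'   JSON path.
#' @return List with the in-memory results (`elements`, `pairs`, `regions`,
#'   `stats`, optionally `cnvs`) and the written file paths (`files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (req in c("rmsk", "genome")) {
    assert_that(!is.null(config[[req]]), "config lacks '%s'", req)
    assert_that(file.exists(config[[req]]),
                "input file missing: %s (%s)", config[[req]], req)
  }
  params <- utils::modifyList(default_params(), config$params %||% list())
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- read_rmsk_table(config$rmsk)
  genome <- read_genome_fasta(config$genome)
  bad_chrom <- setdiff(unique(ann$chrom), names(genome))
  assert_that(length(bad_chrom) == 0L,
              "chromosomes in %s absent from %s: %s", config$rmsk,
              config$genome, paste(bad_chrom, collapse = ", "))
  segdups <- if (!is.null(config$segdups)) {
    read_segdup_table(config$segdups)
  } else NULL

  elements <- join_fragments(ann, params$max_join_gap)
  pairs <- find_herv_pairs(
    elements, genome, segdups,
    min_length = params$min_length, min_sep = params$min_sep,
    max_sep = params$max_sep, min_identity = params$min_identity,
    min_aln_length = params$min_aln_length,
    same_family_only = isTRUE(params$same_family_only))
  regions <- condense_regions(pairs)
  stats <- coverage_stats(regions, genome_lengths(genome))

  inputs <- list(rmsk = config$rmsk, genome = config$genome)
  if (!is.null(config$segdups)) inputs$segdups <- config$segdups
  hdr <- provenance_header("pairs", params, inputs)
  files <- list(
    pairs = file.path(out_dir, "pairs.tsv"),
    elements = file.path(out_dir, "elements.bed"),
    regions = file.path(out_dir, "regions.bed"),
    stats = file.path(out_dir, "coverage.tsv")
  )
  pair_cols <- setdiff(names(pairs), "alignment")
  write_tsv_with_header(pairs[, pair_cols, drop = FALSE], files$pairs, hdr)
  kept <- filter_elements_by_length(elements, params$min_length)
  write_bed(kept, files$elements)
  write_bed(regions, files$regions)
  write_tsv_with_header(stats$per_chrom, files$stats,
                        provenance_header("coverage", params, inputs))

  result <- list(elements = elements, pairs = pairs, regions = regions,
                 stats = stats, files = files, params = params)
  if (!is.null(config$cnvs)) {
    assert_that(file.exists(config$cnvs),
                "input file missing: %s (cnvs)", config$cnvs)
    cnvs <- read_cnv_table(config$cnvs)
    flagged <- match_cnvs_to_pairs(cnvs, kept, pairs)
    files$flagged <- file.path(out_dir, "cnvs_flagged.tsv")
    inputs$cnvs <- config$cnvs
    write_tsv_with_header(flagged, files$flagged,
                          provenance_header("crossref", params, inputs))
    result$cnvs <- flagged
    result$files <- files
  }
  result
}
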