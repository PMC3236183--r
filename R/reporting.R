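# Run records mirror the flat relational schema of the original
# assembly-evaluation database: one row per (run, genome_region), with the
# run-level descriptors and assembly statistics repeated on each row and
# the per-region metric fields alongside.

run_fields <- c("dataset_id_a", "dataset_id_b", "assembler",
                "assembler_parameters", "k_value", "processors_used",
                "runtime", "processor_time", "max_memory_used",
                "final_disk_space_used")

stat_fields <- c("n_contigs", "total_contig_length",
                 "average_contig_length", "contig_n50",
                 "largest_contig_length", "contigs_gt_1000",
                 "contigs_gt_5000", "n_scaffolds", "total_scaffold_length",
                 "average_scaffold_length", "scaffold_n50",
                 "largest_scaffold_length")

metric_fields <- c("genome_region", "ambiguous_bases", "error_rate",
                   "indel_rate", "mismatch_rate", "misassembly_rate",
                   "misassembled_contigs", "misassembled_contig_bases",
                   "internal_overlaps", "internal_gaps", "representation",
                   "n_gaps", "n_negative_gaps", "avg_gap_size",
                   "avg_negative_gap_size", "total_gap_bases",
                   "n_captured_gaps", "avg_captured_gap_size",
                   "total_captured_gap_bases", "unaligned_contigs",
                   "unaligned_bases", "ambiguously_aligned_contigs",
                   "ambiguously_aligned_bases")

record_fields <- function() c(run_fields, stat_fields, metric_fields)

#' Assemble flat run records from an evaluation
#'
#' Combines run metadata, assembly statistics and an evaluation's metric
#' records into the flat one-row-per-(run, genome_region) table used by
#' [write_records()]. Resource fields (`runtime`, `max_memory_used`, ...)
#' are `NA` unless supplied: no assembler is bundled, they exist for runs
#' recorded around external assembler invocations.
#'
#' @param evaluation an `assembly_evaluation` from [evaluate_assembly()].
#' @param stats an `assembly_stats` from [summarize_assembly()].
#' @param dataset_id_a,dataset_id_b read-dataset identifiers (a study's
#'   paired A/B dataset design; `dataset_id_b` may be `NA`).
#' @param assembler,assembler_parameters,k_value,processors_used,runtime,processor_time,max_memory_used,final_disk_space_used
#'   run descriptors; all optional.
#' @return data.frame of class `asm_run_records`.
#' @export
run_record <- function(evaluation, stats, dataset_id_a,
                       dataset_id_b = NA_character_,
                       assembler = NA_character_,
                       assembler_parameters = NA_character_,
                       k_value = NA_real_, processors_used = NA_real_,
                       runtime = NA_real_, processor_time = NA_real_,
                       max_memory_used = NA_real_,
                       final_disk_space_used = NA_real_) {
  stopifnot(inherits(evaluation, "assembly_evaluation"),
            inherits(stats, "assembly_stats"),
            is.character(dataset_id_a), nzchar(dataset_id_a))
  met <- evaluation$records[, metric_fields, drop = FALSE]
  run <- data.frame(dataset_id_a = dataset_id_a,
                    dataset_id_b = dataset_id_b, assembler = assembler,
                    assembler_parameters = assembler_parameters,
                    k_value = k_value, processors_used = processors_used,
                    runtime = runtime, processor_time = processor_time,
                    max_memory_used = max_memory_used,
                    final_disk_space_used = final_disk_space_used,
                    stringsAsFactors = FALSE)
  out <- cbind(run[rep(1L, nrow(met)), , drop = FALSE],
               as.data.frame(stats)[rep(1L, nrow(met)), , drop = FALSE],
               met)
  rownames(out) <- NULL
  class(out) <- c("asm_run_records", "data.frame")
  out
}

#' Bind run-record tables
#' @param ... `asm_run_records` tables.
#' @return one combined `asm_run_records` table.
#' @export
bind_records <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("asm_run_records", "data.frame")
  out
}

#' Write and read run records (TSV, JSON or SQLite)
#'
#' All three backends are lossless round trips of the flat record table;
#' column names are the snake_cased schema fields. The SQLite backend
#' stores one table `runs` (schema DDL in the package's `extdata/`
#' cookbook); it replaces a relational server deployment with a
#' zero-infrastructure file of the same relational shape.
#'
#' @param records an `asm_run_records` data.frame (or any data.frame with
#'   the schema's columns).
#' @param path output file.
#' @param format `"tsv"`, `"json"` or `"sqlite"` (default guessed from
#'   the file extension).
#' @return `path` invisibly (`write_records`); the records
#'   (`read_records`).
#' @export
write_records <- function(records, path,
                          format = guess_format(path)) {
  format <- match.arg(format, c("tsv", "json", "sqlite"))
  records <- as.data.frame(records)
  missing <- setdiff(record_fields(), names(records))
  for (m in missing) records[[m]] <- NA
  records <- records[, record_fields(), drop = FALSE]
  switch(format,
    tsv = write.table(records, path, sep = "\t", quote = FALSE,
                      row.names = FALSE, na = "NA"),
    json = jsonlite::write_json(records, path, digits = NA,
                                na = "null", auto_unbox = FALSE),
    sqlite = {
      con <- DBI::dbConnect(RSQLite::SQLite(), path)
      on.exit(DBI::dbDisconnect(con))
      DBI::dbWriteTable(con, "runs", records, overwrite = TRUE)
    })
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("tsv", "json", "sqlite"))
  out <- switch(format,
    tsv = read.delim(path, stringsAsFactors = FALSE, na.strings = "NA"),
    json = as.data.frame(jsonlite::read_json(path,
                                             simplifyVector = TRUE)),
    sqlite = {
      con <- DBI::dbConnect(RSQLite::SQLite(), path)
      on.exit(DBI::dbDisconnect(con))
      DBI::dbReadTable(con, "runs")
    })
  chr_fields <- c("dataset_id_a", "dataset_id_b", "assembler",
                  "assembler_parameters", "genome_region")
  for (f in intersect(chr_fields, names(out)))
    out[[f]] <- as.character(out[[f]])
  # all-NA columns come back typeless from JSON; restore schema numerics
  for (f in intersect(setdiff(record_fields(), chr_fields), names(out)))
    out[[f]] <- as.numeric(out[[f]])
  class(out) <- c("asm_run_records", "data.frame")
  out
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tsv = "tsv", txt = "tsv", json = "json",
         sqlite = "sqlite", db = "sqlite", sqlite3 = "sqlite",
         stop("cannot guess record format from '", path,
              "'; pass format=", call. = FALSE))
}

#' Compare runs: per-group mean, sd and n of one metric
#'
#' The summary used for cross-platform/assembler comparison figures:
#' arithmetic means of a numeric metric per group, with standard
#' deviations (`NA` for singleton groups) and group sizes, in
#' deterministic (alphabetical) group order.
#'
#' @param records run-record table.
#' @param group_by grouping column name (e.g. `"assembler"`).
#' @param metric numeric metric column name (e.g. `"representation"`).
#' @param region restrict to one `genome_region` (default `"all"`;
#'   `NULL` uses every row).
#' @return data.frame with columns `group_by`, `mean`, `sd`, `n`.
#' @export
compare_runs <- function(records, group_by, metric, region = "all") {
  records <- as.data.frame(records)
  if (!group_by %in% names(records))
    stop("unknown grouping field '", group_by, "'", call. = FALSE)
  if (!metric %in% names(records))
    stop("unknown metric field '", metric, "'", call. = FALSE)
  if (!is.numeric(records[[metric]]))
    stop("metric '", metric, "' is not numeric", call. = FALSE)
  if (!is.null(region) && "genome_region" %in% names(records))
    records <- records[records$genome_region == region, , drop = FALSE]
  if (nrow(records) == 0L) {
    out <- data.frame(group = character(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0))
    names(out)[1] <- group_by
    return(out)
  }
  g <- factor(records[[group_by]])
  out <- data.frame(group = levels(g),
                    mean = as.numeric(tapply(records[[metric]], g, mean)),
                    sd = as.numeric(tapply(records[[metric]], g, sd)),
                    n = as.integer(table(g)))
  out$sd[out$n == 1L] <- NA_real_
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out[order(out[[group_by]]), , drop = FALSE]
}

#' Bar plot of a compare_runs() table
#'
#' A minimal static replacement for interactive graphing: one bar per
#' group with +/- 1 sd whiskers.
#'
#' @param tab output of [compare_runs()].
#' @param metric label for the y axis.
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @importFrom graphics barplot arrows
#' @export
plot_comparison <- function(tab, metric = "value", ...) {
  mids <- barplot(tab$mean, names.arg = tab[[1]], ylab = metric,
                  ylim = c(0, max(tab$mean + ifelse(is.na(tab$sd), 0,
                                                    tab$sd)) * 1.1), ...)
  has_sd <- !is.na(tab$sd) & tab$sd > 0
  if (any(has_sd))
    arrows(mids[has_sd], tab$mean[has_sd] - tab$sd[has_sd],
           mids[has_sd], tab$mean[has_sd] + tab$sd[has_sd],
           angle = 90, code = 3, length = 0.05)
  invisible(mids)
}
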