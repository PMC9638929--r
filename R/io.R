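# Tabular outputs are plain TSV with '#'-prefixed metadata headers so
# results stay diffable and language-neutral.

provenance_header <- function(extra = character()) {
  c(sprintf("# polyprof %s",
            as.character(utils::packageVersion("polyprof"))),
    sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

write_tsv_with_header <- function(df, path, extra = character(),
                                  timestamp = TRUE) {
  hdr <- if (timestamp) provenance_header(extra) else
    c(sprintf("# polyprof %s",
              as.character(utils::packageVersion("polyprof"))), extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_skip_comments <- function(path, header = TRUE, sep = "") {
  utils::read.table(path, header = header, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a profile trace from a delimited file
#'
#' Accepts a headered file with columns `position` and `absorbance`
#' (any order, extra columns ignored) or, with `header = FALSE`, a
#' plain two-column file read as (position, absorbance).  Lines
#' starting with `#` are skipped.  Non-monotone positions are rejected
#' with the offending row number.
#'
#' @param path File path.
#' @param header Whether the file has a header row (default `TRUE`).
#' @param sep Field separator; default `""` splits on any whitespace
#'   and also handles commas via auto-detection of the first data line.
#' @return A [profile_trace()].
#' @export
read_trace <- function(path, header = TRUE, sep = NULL) {
  if (!file.exists(path)) pp_stop_invalid(sprintf("no such file: %s", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 20)
    first <- first[!startsWith(first, "#") & nzchar(first)]
    sep <- if (length(first) > 0 && grepl(",", first[1])) "," else ""
  }
  df <- tryCatch(read_tsv_skip_comments(path, header = header, sep = sep),
                 error = function(e)
                   pp_stop_invalid(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  if (header) {
    if (!all(c("position", "absorbance") %in% names(df)))
      pp_stop_invalid("trace file must have columns 'position' and 'absorbance'")
  } else {
    if (ncol(df) < 2)
      pp_stop_invalid("headerless trace file must have two columns")
    names(df)[1:2] <- c("position", "absorbance")
  }
  profile_trace(df$position, df$absorbance)
}

#' Write a profile trace to TSV
#'
#' @param trace A [profile_trace()].
#' @param path Output path.
#' @param extra Extra `#` metadata lines.
#' @export
write_trace <- function(trace, path, extra = character()) {
  if (!is_profile_trace(trace))
    pp_stop_invalid("trace must be a profile_trace")
  df <- data.frame(position = sprintf("%.17g", trace$position),
                   absorbance = sprintf("%.17g", trace$absorbance))
  write_tsv_with_header(df, path, extra)
  invisible(path)
}

validate_counts <- function(counts) {
  counts <- as.data.frame(counts)
  if ("length" %in% names(counts) && !"length_nt" %in% names(counts))
    names(counts)[names(counts) == "length"] <- "length_nt"
  req <- c("gene_id", "length_nt", "fp_count", "rna_count")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0)
    pp_stop_invalid(sprintf("count table is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  counts <- counts[, req]
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0)
    pp_stop_invalid(sprintf("duplicated gene_id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  if (any(counts$length_nt <= 0))
    pp_stop_invalid("all gene lengths must be positive")
  if (any(counts$fp_count < 0) || any(counts$rna_count < 0))
    pp_stop_invalid("counts must be non-negative")
  if (any(!is.finite(counts$fp_count)) || any(!is.finite(counts$rna_count)))
    pp_stop_invalid("counts must be finite")
  counts
}

#' Read a per-gene count table
#'
#' Expects a delimited file with header columns `gene_id`, `length`
#' (or `length_nt`, in nucleotides), `fp_count` and `rna_count`, in
#' any order.  With `rpkm = TRUE` the `fp_count`/`rna_count` columns
#' are interpreted as RPKM values and converted to effective counts
#' (`rpkm * length_kb * depth / 1e6`); since every downstream quantity
#' is ratio-based, the nominal depth only sets the scale.
#'
#' @param path File path (TSV/CSV; `#` comment lines skipped).
#' @param rpkm Whether the count columns are RPKM values.
#' @param depth Nominal depth for RPKM conversion (default 1e6).
#' @param sep Field separator; auto-detected by default.
#' @return Validated count table (data frame with columns `gene_id`,
#'   `length_nt`, `fp_count`, `rna_count`).
#' @export
read_counts <- function(path, rpkm = FALSE, depth = 1e6, sep = NULL) {
  if (!file.exists(path)) pp_stop_invalid(sprintf("no such file: %s", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 20)
    first <- first[!startsWith(first, "#") & nzchar(first)]
    sep <- if (length(first) > 0 && grepl(",", first[1])) "," else ""
  }
  df <- tryCatch(read_tsv_skip_comments(path, header = TRUE, sep = sep),
                 error = function(e)
                   pp_stop_invalid(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  df <- validate_counts(df)
  if (rpkm) {
    df$fp_count <- df$fp_count * (df$length_nt / 1000) * depth / 1e6
    df$rna_count <- df$rna_count * (df$length_nt / 1000) * depth / 1e6
  }
  df
}

#' Write a peak-volume vector to TSV
#'
#' @param volumes Named peak-volume vector.
#' @param path Output path.
#' @param extra Extra `#` metadata lines.
#' @export
write_volumes <- function(volumes, path, extra = character()) {
  df <- data.frame(peak = names(volumes),
                   volume = sprintf("%.17g", as.numeric(volumes)))
  write_tsv_with_header(df, path, extra)
  invisible(path)
}

#' Read a peak-volume vector from TSV
#'
#' @param path Path to a file written by [write_volumes()] (columns
#'   `peak`, `volume`).
#' @return Named numeric vector.
#' @export
read_volumes <- function(path) {
  df <- read_tsv_skip_comments(path, header = TRUE, sep = "\t")
  if (!all(c("peak", "volume") %in% names(df)))
    pp_stop_invalid("volume file must have columns 'peak' and 'volume'")
  stats::setNames(as.numeric(df$volume), as.character(df$peak))
}

#' Serialise a fitted profile model to a flat text format
#'
#' One peak per row (`label`, `mu`, `sigma`, `s`) followed by the four
#' background terms, so fits are diffable and re-loadable with
#' [read_profile_model()].
#'
#' @param model A [profile_model()].
#' @param path Output path.
#' @export
write_profile_model <- function(model, path) {
  if (!inherits(model, "profile_model"))
    pp_stop_invalid("model must be a profile_model")
  bg <- model$background
  df <- rbind(
    data.frame(label = model$peaks$label,
               mu = sprintf("%.17g", model$peaks$mu),
               sigma = sprintf("%.17g", model$peaks$sigma),
               s = sprintf("%.17g", model$peaks$s)),
    data.frame(label = c("@A", "@k", "@m", "@c"),
               mu = "", sigma = "",
               s = sprintf("%.17g", c(bg$A, bg$k, bg$m, bg$c))))
  write_tsv_with_header(df, path,
                        extra = sprintf("# rms=%.17g", model$rms))
  invisible(path)
}

#' Read a profile model written by [write_profile_model()]
#'
#' @param path File path.
#' @return A [profile_model()].
#' @export
read_profile_model <- function(path) {
  lines <- readLines(path)
  rms <- NA_real_
  rms_line <- grep("^# rms=", lines, value = TRUE)
  if (length(rms_line) > 0)
    rms <- as.numeric(sub("^# rms=", "", rms_line[1]))
  df <- read_tsv_skip_comments(path, header = TRUE, sep = "\t")
  bg_rows <- startsWith(df$label, "@")
  bg <- stats::setNames(as.numeric(df$s[bg_rows]),
                        sub("^@", "", df$label[bg_rows]))
  pk <- df[!bg_rows, ]
  profile_model(data.frame(label = as.character(pk$label),
                           mu = as.numeric(pk$mu),
                           sigma = as.numeric(pk$sigma),
                           s = as.numeric(pk$s)),
                background = as.list(bg), rms = rms)
}

#' Run the end-to-end polysome modelling pipeline
#'
#' Reads a count table, models the peak-volume vector, renders the
#' modelled trace, and (optionally) compares the result against a
#' reference volume vector using an RMSD null.  If `reference_rna` is
#' supplied, its `rna_count` column replaces the count table's own RNA
#' data (matched by `gene_id`; genes missing from the reference get
#' zero RNA and are excluded with a QC note), reproducing the
#' reference-RNA substitution workflow.
#'
#' @param counts Count table (data frame) or path to one.
#' @param params A [cell_params()] object (default yeast preset).
#' @param include_idle Whether to add inactive ribosomes
#'   ([add_inactive()]).
#' @param n_max Highest modelled peak.
#' @param reference_rna Optional count table (or path) whose
#'   `rna_count` column substitutes the input's RNA data.
#' @param location_model Optional `peak_location_model` for rendering;
#'   default `position = 20 ln(index) + 30`.
#' @param width_factor Rendering width factor.
#' @param reference_volumes Optional named volume vector to compare
#'   against (RMSD, and a P-value when `null` is given).
#' @param null Optional [fit_null()] result for the P-value.
#' @param out_dir Optional directory; when given, writes
#'   `volumes.tsv`, `modelled_trace.tsv` and `qc.tsv` there.
#' @return List with elements `volumes`, `trace`, `qc` (named list of
#'   QC metrics) and, when a reference was supplied, `comparison`
#'   (list with `rmsd` and possibly `p_value`).
#' @export
run_pipeline <- function(counts, params = cell_params("yeast"),
                         include_idle = TRUE, n_max = 20,
                         reference_rna = NULL,
                         location_model = NULL, width_factor = 0.25,
                         reference_volumes = NULL, null = NULL,
                         out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  counts <- validate_counts(counts)
  if (!is.null(reference_rna)) {
    if (is.character(reference_rna)) reference_rna <- read_counts(reference_rna)
    reference_rna <- validate_counts(reference_rna)
    m <- match(counts$gene_id, reference_rna$gene_id)
    counts$rna_count <- ifelse(is.na(m), 0, reference_rna$rna_count[m])
  }
  vol <- model_polysome(counts, params, include_idle = include_idle,
                        n_max = n_max)
  if (is.null(location_model))
    location_model <- new_peak_location_model(20, 30, peak_index_value(names(vol)))
  trace <- render_modelled_profile(
    vol, location_model, width_factor = width_factor,
    small_subunit_fraction = params$small_subunit_fraction)
  qc <- list(
    n_genes = nrow(counts),
    excluded_genes = length(attr(vol, "excluded_genes")),
    excluded_fp_fraction = attr(vol, "excluded_fp_fraction"),
    over_cap_fraction = attr(vol, "over_cap_fraction"),
    pooled_mass = attr(vol, "pooled_mass"))
  out <- list(volumes = vol, trace = trace, qc = qc)
  if (!is.null(reference_volumes)) {
    cmp <- list(rmsd = rmsd(vol, reference_volumes))
    if (!is.null(null)) cmp$p_value <- rmsd_pvalue(cmp$rmsd, null)
    out$comparison <- cmp
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(sprintf("# preset=%s include_idle=%s n_max=%d",
                      params$preset, include_idle, n_max))
    write_volumes(vol, file.path(out_dir, "volumes.tsv"), extra = meta)
    write_trace(trace, file.path(out_dir, "modelled_trace.tsv"), extra = meta)
    qdf <- data.frame(metric = names(qc),
                      value = vapply(qc, function(x)
                        sprintf("%.10g", as.numeric(x)), character(1)))
    write_tsv_with_header(qdf, file.path(out_dir, "qc.tsv"), extra = meta)
  }
  out
}

#' Load the packaged synthetic known-good volume collection
#'
#' A small collection of peak-volume vectors generated by the
#' synthetic-fixture module (see `inst/extdata/known_good_volumes.tsv`,
#' which records the generating spec in its header).  It allows RMSD
#' P-values to be computed out of the box; it is synthetic and should
#' be replaced by the user's own known-good datasets for real QC work.
#'
#' @return List of named peak-volume vectors.
#' @export
known_good_volumes <- function() {
  path <- system.file("extdata", "known_good_volumes.tsv",
                      package = "polyprof")
  df <- read_tsv_skip_comments(path, header = TRUE, sep = "\t")
  peaks <- df$peak
  lapply(names(df)[-1], function(cn)
    stats::setNames(as.numeric(df[[cn]]), as.character(peaks)))
}
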