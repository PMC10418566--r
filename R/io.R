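#' Read a gene annotation and keep protein-coding genes
#'
#' Parses either a gencode-dialect GTF (1-based inclusive coordinates,
#' attribute keys `gene_id`, `gene_type`, optionally `gene_name`) or a
#' BED-like headered TSV as written by [write_gene_annotation()]. Coordinates
#' are normalized to the 0-based half-open convention used throughout the
#' package. The TSS is the `start` of the body for `+` genes and `end - 1`
#' for `-` genes.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, sorted by `(chrom, tss)`. Only protein-coding
#'   genes are returned.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gtf") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    idx <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9)) {
      abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                    idx[which(nf != 9)[1]], nf[nf != 9][1]))
    }
    feat <- vapply(fields, `[[`, "", 3)
    gene_rows <- which(feat == "gene")
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(paste0(key, " \"([^\"]+)\""), a))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }
    recs <- map(gene_rows, function(i) {
      f <- fields[[i]]
      start1 <- suppressWarnings(as.numeric(f[4]))
      end1 <- suppressWarnings(as.numeric(f[5]))
      if (is.na(start1) || is.na(end1)) {
        abort(sprintf("malformed GTF line %d: non-numeric coordinates", idx[i]))
      }
      tibble(
        gene_id = attr_get(f[9], "gene_id"),
        symbol = attr_get(f[9], "gene_name"),
        chrom = f[1],
        start = start1 - 1,  # 1-based inclusive -> 0-based half-open
        end = end1,
        strand = f[7],
        gene_type = attr_get(f[9], "gene_type")
      )
    }) |> list_rbind()
    if (nrow(recs) == 0) abort("no gene records in GTF")
    genes <- filter(recs, .data$gene_type == "protein_coding")
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    needed <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(needed %in% names(genes))) {
      abort(paste0("BED-like gene table must have columns: ",
                   paste(needed, collapse = ", ")))
    }
    if ("gene_type" %in% names(genes)) {
      genes <- filter(genes, .data$gene_type == "protein_coding")
    }
    if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  }
  if (nrow(genes) == 0) abort("no protein-coding gene records found")
  genes <- genes |>
    mutate(symbol = coalesce(.data$symbol, .data$gene_id),
           tss = ifelse(.data$strand == "-", .data$end - 1, .data$start)) |>
    select("gene_id", "symbol", "chrom", "start", "end", "strand", "tss") |>
    arrange(.data$chrom, .data$tss)
  validate_intervals(genes)
  genes
}

#' Write a gene annotation as a BED-like headered TSV
#'
#' @param genes Tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- genes |>
    mutate(gene_type = "protein_coding") |>
    select("gene_id", "symbol", "chrom", "start", "end", "strand", "gene_type")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a CpG probe manifest
#'
#' Expects a headered TSV with columns `probe_id`, `chrom`, `pos` (0-based bp)
#' and `island`. The island column is normalized to a logical: any value
#' containing "island" (case-insensitive), `TRUE` or `1` marks island
#' membership.
#'
#' @param path Path to the manifest.
#' @return Tibble with `probe_id`, `chrom`, `pos`, `in_island`, sorted by
#'   `(chrom, pos)`.
#' @export
read_probe_manifest <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("empty or missing probe manifest: ", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) abort("probe manifest has no rows")
  needed <- c("probe_id", "chrom", "pos", "island")
  if (!all(needed %in% names(tab))) {
    abort(paste0("probe manifest must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(tab$probe_id)) {
    abort(paste0("duplicated probe_id: ", tab$probe_id[duplicated(tab$probe_id)][1]))
  }
  pos <- suppressWarnings(as.numeric(tab$pos))
  if (anyNA(pos)) {
    abort(paste0("non-numeric position for probe ", tab$probe_id[which(is.na(pos))[1]]))
  }
  tab |>
    mutate(pos = pos,
           in_island = grepl("island", as.character(.data$island), ignore.case = TRUE) |
             as.character(.data$island) %in% c("TRUE", "1")) |>
    select("probe_id", "chrom", "pos", "in_island") |>
    arrange(.data$chrom, .data$pos)
}

#' Write a probe manifest
#' @param probes Tibble as from [read_probe_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_manifest <- function(probes, path) {
  out <- probes |>
    mutate(island = ifelse(.data$in_island, "Island", "OpenSea")) |>
    select("probe_id", "chrom", "pos", "island")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds row identifiers, the header holds sample identifiers.
#' Missing cells (empty or `NA`) become `NA`. For `kind = "methylation_beta"`
#' values outside `[0, 1]` are an error naming the offending cell.
#'
#' @param path Path to the TSV.
#' @param kind One of `"expression"`, `"methylation_beta"`, `"log_counts"`.
#' @return A numeric matrix with dimnames; `kind` is stored as an attribute.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation_beta", "log_counts")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  if (length(lines) < 2) abort("matrix file needs a header and at least one row")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1]])
  bad <- which(lengths(parts) != ncols)
  if (length(bad) > 0) {
    abort(sprintf("ragged matrix: line %d has %d fields, expected %d",
                  bad[1], lengths(parts)[bad[1]], ncols))
  }
  col_ids <- parts[[1]][-1]
  row_ids <- vapply(parts[-1], `[[`, "", 1)
  if (anyDuplicated(row_ids)) abort("duplicated row ids in matrix")
  if (anyDuplicated(col_ids)) abort("duplicated column ids in matrix")
  vals <- vapply(parts[-1], function(p) {
    v <- p[-1]
    v[v %in% c("", "NA", "nan", "NaN")] <- NA
    suppressWarnings(as.numeric(v))
  }, numeric(ncols - 1))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = 1) else t(vals)
  dimnames(m) <- list(row_ids, col_ids)
  if (kind == "methylation_beta") {
    out_of_range <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(out_of_range) > 0) {
      abort(sprintf("beta value %g out of [0,1] at row '%s', column '%s'",
                    m[out_of_range[1, , drop = FALSE]],
                    row_ids[out_of_range[1, 1]], col_ids[out_of_range[1, 2]]))
    }
  }
  attr(m, "kind") <- kind
  m
}

#' Write a feature-by-sample matrix as TSV
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name for the first (row-identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "id") {
  df <- as_tibble(m, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read chromatin loops from BEDPE
#'
#' Standard 6+ column BEDPE (no header). Trans-chromosomal rows are parsed
#' and flagged `is_cis = FALSE`; all downstream overlap statistics use cis
#' loops only.
#'
#' @param path Path to a BEDPE file.
#' @param source_label Label for the loop source (cell line / assay).
#' @return Tibble with `chrom1,start1,end1,chrom2,start2,end2,source,is_cis`.
#' @export
read_loops <- function(path, source_label = basename(path)) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 6) abort("BEDPE needs at least 6 columns")
  loops <- tibble(
    chrom1 = as.character(tab[[1]]), start1 = as.numeric(tab[[2]]), end1 = as.numeric(tab[[3]]),
    chrom2 = as.character(tab[[4]]), start2 = as.numeric(tab[[5]]), end2 = as.numeric(tab[[6]]),
    source = source_label
  )
  if (any(loops$end1 <= loops$start1) || any(loops$end2 <= loops$start2)) {
    abort("loop anchor with end <= start")
  }
  mutate(loops, is_cis = .data$chrom1 == .data$chrom2)
}

#' Read a labeled interval annotation from BED
#'
#' @param path Path to a BED file (no header, >= 4 columns).
#' @param label_column Index of the column holding the label (default 4).
#' @return Tibble with `chrom`, `start`, `end`, `label`; labels are kept
#'   verbatim (including labels with spaces such as "Low Signal").
#' @export
read_interval_annotation <- function(path, label_column = 4) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < label_column) abort("BED has fewer columns than label_column")
  out <- tibble(chrom = as.character(tab[[1]]),
                start = as.numeric(tab[[2]]),
                end = as.numeric(tab[[3]]),
                label = as.character(tab[[label_column]]))
  validate_intervals(out)
  out
}

#' Read a clinical sample table
#'
#' Headered TSV with columns `sample_id`, `context`, `sample_type` and
#' optionally `OS` (event 0/1) and `OS.time` (days).
#'
#' @param path Path to the TSV.
#' @return Tibble with `sample_id`, `context`, `sample_type`, `os_event`,
#'   `os_time`.
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("sample_id", "context", "sample_type")
  if (!all(needed %in% names(tab))) {
    abort(paste0("sample table must have columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) abort("duplicated sample_id")
  out <- tibble(sample_id = as.character(tab$sample_id),
                context = as.character(tab$context),
                sample_type = as.character(tab$sample_type),
                os_event = if ("OS" %in% names(tab)) as.numeric(tab$OS) else NA_real_,
                os_time = if ("OS.time" %in% names(tab)) as.numeric(tab$OS.time) else NA_real_)
  if (any(!is.na(out$os_time) & out$os_time < 0)) abort("negative os_time")
  out
}

#' Write a clinical sample table
#' @param samples Tibble as from [read_sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  out <- samples |>
    select("sample_id", "context", "sample_type",
           OS = "os_event", OS.time = "os_time")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# every interval must satisfy 0 <= start < end
validate_intervals <- function(df) {
  if (any(df$start < 0)) abort("negative interval start")
  if (any(df$end <= df$start)) abort("interval with end <= start")
  invisible(df)
}
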