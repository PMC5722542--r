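#' GDSC CSV dialect description
#'
#' Describes the column layout of a release CSV so the same reader can consume
#' both real GDSC-style exports and synthetic fixtures. The main table is wide:
#' one row per cell line, one column per gene (holding an \code{"x::y"}
#' annotation), per gene fusion (a token), the msi status column (already
#' binary) and one column per drug (named \code{<drug_prefix><drug_id>}) with
#' the measured IC50 on a log scale; empty cells mean the pair was not
#' measured.
#'
#' @param cell_line_col name of the cell-line identifier column.
#' @param gene_cols character vector of gene annotation columns, or NULL to
#'   infer them as every column not claimed by another role.
#' @param fusion_cols columns holding gene-fusion tokens.
#' @param msi_col name of the microsatellite-instability column (0/1), or NULL.
#' @param drug_prefix prefix identifying drug response columns.
#' @param response_scale \code{"log10"} or \code{"ln"}; \code{"ln"} responses
#'   are converted to log10 micromolar on read.
#' @param wt_cna_token literal copy-number token denoting a wild-type copy
#'   number (matched case-insensitively after trimming).
#' @param fusion_wt_tokens tokens denoting a non-detected fusion.
#' @return an object of class \code{gdsc_dialect}.
#' @export
gdsc_dialect <- function(cell_line_col = "cell_line",
                         gene_cols = NULL,
                         fusion_cols = c("BCR_ABL", "MLL_AFF1", "EWS_FLI1"),
                         msi_col = "msi",
                         drug_prefix = "IC50_",
                         response_scale = c("log10", "ln"),
                         wt_cna_token = "0<cna<8",
                         fusion_wt_tokens = c("wt", "fusion not-detected")) {
  response_scale <- match.arg(response_scale)
  structure(list(cell_line_col = cell_line_col,
                 gene_cols = gene_cols,
                 fusion_cols = fusion_cols,
                 msi_col = msi_col,
                 drug_prefix = drug_prefix,
                 response_scale = response_scale,
                 wt_cna_token = wt_cna_token,
                 fusion_wt_tokens = fusion_wt_tokens),
            class = "gdsc_dialect")
}

norm_token <- function(x) tolower(trimws(x))

#' Parse an 'x::y' variant/copy-number annotation into a binary mutation flag
#'
#' A gene is called mutated (1) if the coding-variant token is anything other
#' than \code{wt}/\code{na}, or if the copy-number token differs from the
#' wild-type copy-number token; otherwise wild-type (0). Token comparison is
#' case-insensitive and whitespace-trimmed.
#'
#' @param coding_variant character vector of coding-variant tokens (the 'x').
#' @param copy_number character vector of copy-number tokens (the 'y').
#' @param wt_cna_token the literal wild-type copy-number token.
#' @return integer vector of 0/1 flags.
#' @export
parse_variant_annotation <- function(coding_variant, copy_number,
                                     wt_cna_token = "0<cna<8") {
  cv <- norm_token(coding_variant)
  cn <- norm_token(copy_number)
  if (any(!nzchar(cv)) || any(!nzchar(cn)))
    stop("empty variant annotation token")
  as.integer(!(cv %in% c("wt", "na")) | cn != norm_token(wt_cna_token))
}

#' Parse a gene-fusion status token into a binary flag
#'
#' Returns 0 for tokens in the not-detected vocabulary; any other token is
#' taken as the identified fusion (1). Unknown tokens therefore count as
#' detected, with a message so surprising vocabularies are visible.
#'
#' @param token character vector of fusion tokens.
#' @param wt_tokens vocabulary of not-detected tokens.
#' @param known additional tokens known to denote a detected fusion (no
#'   message is emitted for these, e.g. the fusion's own name).
#' @return integer vector of 0/1 flags.
#' @export
parse_fusion_status <- function(token,
                                wt_tokens = c("wt", "fusion not-detected"),
                                known = character()) {
  tok <- norm_token(token)
  if (any(!nzchar(tok))) stop("empty fusion token")
  flag <- as.integer(!(tok %in% norm_token(wt_tokens)))
  unknown <- unique(tok[flag == 1L & !(tok %in% norm_token(known))])
  if (length(unknown))
    message("fusion tokens treated as detected: ",
            paste(unknown, collapse = ", "))
  flag
}

#' Convert a natural-log micromolar concentration to log10
#'
#' Screen exports report ln(IC50 in uM); all internal work is in log10
#' micromolar so response differences read as orders of magnitude.
#'
#' @param value numeric vector of natural-log micromolar concentrations.
#' @return the same concentrations in log10 micromolar.
#' @export
convert_ln_to_log10 <- function(value) {
  if (any(!is.finite(value))) stop("non-finite logIC50 value")
  value / log(10)
}

#' Construct a release-versioned pharmacogenomic dataset
#'
#' @param tag release label.
#' @param features binary integer matrix, cell lines x features, with unique
#'   dimnames.
#' @param responses data.frame with columns drug_id, cell_line_id, log_ic50
#'   (log10 micromolar), at most one row per (drug, cell line).
#' @param drug_metadata optional data.frame with columns drug_id, name, class
#'   (class in cytotoxic/targeted/unknown).
#' @return an object of class \code{dataset_release}.
#' @export
dataset_release <- function(tag, features, responses, drug_metadata = NULL) {
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            !is.null(colnames(features)))
  if (anyDuplicated(rownames(features)))
    stop("duplicate cell line ids in feature matrix")
  if (anyDuplicated(colnames(features)))
    stop("duplicate feature names")
  if (anyNA(features) || !all(features %in% c(0L, 1L)))
    stop("feature values must be 0/1 with no missing entries")
  storage.mode(features) <- "integer"
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "cell_line_id", "log_ic50") %in% names(responses)))
  responses <- responses[, c("drug_id", "cell_line_id", "log_ic50")]
  responses$drug_id <- as.character(responses$drug_id)
  responses$cell_line_id <- as.character(responses$cell_line_id)
  dup <- duplicated(responses[, c("drug_id", "cell_line_id")])
  if (any(dup)) {
    d <- responses[which(dup)[1L], ]
    stop(sprintf("duplicate response record for drug %s, cell line %s",
                 d$drug_id, d$cell_line_id))
  }
  if (any(!is.finite(responses$log_ic50)))
    stop("non-finite log_ic50 in responses")
  missing_cl <- setdiff(responses$cell_line_id, rownames(features))
  if (length(missing_cl))
    stop("cell lines in responses absent from features: ",
         paste(utils::head(missing_cl, 5), collapse = ", "))
  if (!is.null(drug_metadata)) {
    drug_metadata <- as.data.frame(drug_metadata, stringsAsFactors = FALSE)
    stopifnot(all(c("drug_id", "name", "class") %in% names(drug_metadata)))
    drug_metadata$drug_id <- as.character(drug_metadata$drug_id)
    stopifnot(all(drug_metadata$class %in% c("cytotoxic", "targeted", "unknown")))
  }
  structure(list(tag = tag, features = features, responses = responses,
                 drug_metadata = drug_metadata),
            class = "dataset_release")
}

#' @export
print.dataset_release <- function(x, ...) {
  cat(sprintf("<dataset_release '%s'>\n", x$tag))
  cat(sprintf("  %d cell lines x %d binary features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  %d logIC50 records over %d drugs\n",
              nrow(x$responses), length(unique(x$responses$drug_id))))
  invisible(x)
}

#' Read a release CSV in the GDSC dialect
#'
#' Gene annotations are parsed with \code{\link{parse_variant_annotation}},
#' fusions with \code{\link{parse_fusion_status}}, and responses converted to
#' log10 micromolar when the dialect declares an \code{ln} scale. A sidecar
#' file \code{<path minus .csv>_drugs.csv} with columns drug_id, name, class
#' is picked up as drug metadata when present.
#'
#' @param path CSV file path.
#' @param dialect a \code{\link{gdsc_dialect}}.
#' @param tag release label (defaults to the file name).
#' @return a \code{\link{dataset_release}}.
#' @export
read_release <- function(path, dialect = gdsc_dialect(), tag = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(tag)) tag <- sub("\\.csv$", "", basename(path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  cl_col <- dialect$cell_line_col
  if (!cl_col %in% names(tab))
    stop("cell-line column '", cl_col, "' not found in ", path)
  cells <- trimws(tab[[cl_col]])
  if (anyDuplicated(cells))
    stop("duplicate cell line row(s) in ", path, ": ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "),
         " (duplicate drug-cell response records)")

  drug_cols <- grep(paste0("^", dialect$drug_prefix), names(tab), value = TRUE)
  fusion_cols <- intersect(dialect$fusion_cols, names(tab))
  msi_col <- intersect(dialect$msi_col, names(tab))
  gene_cols <- dialect$gene_cols
  if (is.null(gene_cols))
    gene_cols <- setdiff(names(tab), c(cl_col, drug_cols, fusion_cols, msi_col))
  unknown <- setdiff(gene_cols, names(tab))
  if (length(unknown))
    stop("unknown gene column(s): ", paste(unknown, collapse = ", "))

  feat <- matrix(0L, nrow = length(cells),
                 ncol = length(gene_cols) + length(fusion_cols) + length(msi_col),
                 dimnames = list(cells, c(gene_cols, fusion_cols, msi_col)))
  for (g in gene_cols) {
    ann <- tab[[g]]
    bad <- !grepl("::", ann, fixed = TRUE)
    if (any(bad))
      stop(sprintf("malformed annotation (no '::') in column %s, row %d (%s)",
                   g, which(bad)[1L], cells[which(bad)[1L]]))
    parts <- strsplit(ann, "::", fixed = TRUE)
    feat[, g] <- parse_variant_annotation(vapply(parts, `[`, "", 1L),
                                          vapply(parts, `[`, "", 2L),
                                          dialect$wt_cna_token)
  }
  for (f in fusion_cols)
    feat[, f] <- parse_fusion_status(tab[[f]], dialect$fusion_wt_tokens,
                                     known = f)
  if (length(msi_col)) {
    v <- suppressWarnings(as.integer(tab[[msi_col]]))
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("msi column must be 0/1")
    feat[, msi_col] <- v
  }

  resp <- do.call(rbind, lapply(drug_cols, function(dc) {
    v <- tab[[dc]]
    keep <- nzchar(trimws(v)) & !is.na(v)
    if (!any(keep)) return(NULL)
    data.frame(drug_id = sub(paste0("^", dialect$drug_prefix), "", dc),
               cell_line_id = cells[keep],
               log_ic50 = as.numeric(v[keep]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(resp))
    resp <- data.frame(drug_id = character(), cell_line_id = character(),
                       log_ic50 = numeric(), stringsAsFactors = FALSE)
  if (dialect$response_scale == "ln")
    resp$log_ic50 <- convert_ln_to_log10(resp$log_ic50)

  meta_path <- sub("\\.csv$", "_drugs.csv", path)
  meta <- NULL
  if (file.exists(meta_path))
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  message(sprintf("read_release('%s'): %d cell lines, %d features, %d records",
                  tag, nrow(feat), ncol(feat), nrow(resp)))
  dataset_release(tag, feat, resp, meta)
}

#' Write a release in the GDSC dialect
#'
#' Inverse of \code{\link{read_release}}: mutated genes are written as
#' \code{"p.mut::<wt token>"} and wild-type as \code{"wt::<wt token>"},
#' detected fusions as the fusion name, responses in log10 micromolar with
#' full precision so a read/write round trip is exact. Drug metadata, when
#' present, goes to \code{<path minus .csv>_drugs.csv}.
#'
#' @param release a \code{\link{dataset_release}}.
#' @param path output CSV path.
#' @param dialect a \code{\link{gdsc_dialect}} (its response_scale must be
#'   \code{"log10"}).
#' @return \code{path}, invisibly.
#' @export
write_release <- function(release, path, dialect = gdsc_dialect()) {
  stopifnot(inherits(release, "dataset_release"))
  if (dialect$response_scale != "log10")
    stop("write_release only emits log10-scale responses")
  feat <- release$features
  cells <- rownames(feat)
  fusion_cols <- intersect(dialect$fusion_cols, colnames(feat))
  msi_col <- intersect(dialect$msi_col, colnames(feat))
  gene_cols <- setdiff(colnames(feat), c(fusion_cols, msi_col))

  out <- data.frame(row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE,
                    setNames(list(cells), dialect$cell_line_col))
  for (g in gene_cols)
    out[[g]] <- ifelse(feat[, g] == 1L,
                       paste0("p.mut::", dialect$wt_cna_token),
                       paste0("wt::", dialect$wt_cna_token))
  for (f in fusion_cols)
    out[[f]] <- ifelse(feat[, f] == 1L, f, dialect$fusion_wt_tokens[1L])
  if (length(msi_col)) out[[msi_col]] <- feat[, msi_col]

  drugs <- sort(unique(release$responses$drug_id))
  for (d in drugs) {
    rec <- release$responses[release$responses$drug_id == d, ]
    col <- rep("", length(cells))
    col[match(rec$cell_line_id, cells)] <- sprintf("%.17g", rec$log_ic50)
    out[[paste0(dialect$drug_prefix, d)]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(release$drug_metadata))
    utils::write.csv(release$drug_metadata,
                     sub("\\.csv$", "_drugs.csv", path), row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate drug entries to a single kept id
#'
#' Screens occasionally test one compound under two drug ids across releases
#' (e.g. camptothecin); downstream analysis keeps exactly one id per compound.
#'
#' @param release a \code{\link{dataset_release}} with drug metadata.
#' @param keep_map named character vector: names are duplicated compound
#'   names, values the drug id to keep for that compound.
#' @return the release with records of the discarded ids removed.
#' @export
deduplicate_drugs <- function(release, keep_map) {
  stopifnot(inherits(release, "dataset_release"))
  if (!length(keep_map)) return(release)
  meta <- release$drug_metadata
  if (is.null(meta)) stop("deduplicate_drugs requires drug_metadata")
  present <- unique(c(meta$drug_id, release$responses$drug_id))
  absent <- setdiff(unname(keep_map), present)
  if (length(absent))
    stop("keep_map names absent drug id(s): ", paste(absent, collapse = ", "))
  drop <- character()
  for (nm in names(keep_map)) {
    ids <- meta$drug_id[meta$name == nm]
    drop <- c(drop, setdiff(ids, keep_map[[nm]]))
  }
  release$responses <- release$responses[
    !(release$responses$drug_id %in% drop), , drop = FALSE]
  release$drug_metadata <- meta[!(meta$drug_id %in% drop), , drop = FALSE]
  rownames(release$responses) <- NULL
  rownames(release$drug_metadata) <- NULL
  release
}
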