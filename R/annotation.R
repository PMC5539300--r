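#' Feature annotation table
#'
#' Validates and classes a feature annotation table mapping repeat transcript
#' IDs to a two-level TE taxonomy (type within class, e.g. type Alu within
#' class SINE) and coding transcript IDs to gene symbols, with effective
#' lengths for TPM computation.
#'
#' Invariants enforced:
#' * `kind` is `"repeat"` or `"coding"`;
#' * repeat features carry a non-empty `te_type` and `te_class`, and each
#'   `te_type` maps to exactly one `te_class` across the whole table;
#' * coding features carry a non-empty `gene_symbol`;
#' * `effective_length` is positive where present (`NA` allowed; TPM will
#'   refuse features with missing lengths).
#'
#' @param df data.frame with columns `feature_id`, `kind`, `te_type`,
#'   `te_class`, `gene_symbol`, `effective_length`.
#' @return the validated data.frame with class `te_annotation`.
#' @export
te_annotation <- function(df) {
  req <- c("feature_id", "kind", "te_type", "te_class", "gene_symbol",
           "effective_length")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  for (col in req[1:5]) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$effective_length <- as.numeric(df$effective_length)
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup)) stop("duplicate feature IDs in annotation: ", paste(dup, collapse = ", "))
  bad_kind <- setdiff(unique(df$kind), c("repeat", "coding"))
  if (length(bad_kind)) {
    stop("annotation 'kind' must be 'repeat' or 'coding'; found: ",
         paste(bad_kind, collapse = ", "))
  }
  rep_rows <- df$kind == "repeat"
  if (any(rep_rows & (!nzchar(df$te_type) | !nzchar(df$te_class)))) {
    bad <- df$feature_id[rep_rows & (!nzchar(df$te_type) | !nzchar(df$te_class))]
    stop("repeat features lack te_type/te_class: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  cod_rows <- df$kind == "coding"
  if (any(cod_rows & !nzchar(df$gene_symbol))) {
    bad <- df$feature_id[cod_rows & !nzchar(df$gene_symbol)]
    stop("coding features lack gene_symbol: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  tmap <- unique(df[rep_rows, c("te_type", "te_class")])
  dup_type <- unique(tmap$te_type[duplicated(tmap$te_type)])
  if (length(dup_type)) {
    stop("te_type assigned to more than one te_class: ",
         paste(dup_type, collapse = ", "))
  }
  neg <- !is.na(df$effective_length) & df$effective_length <= 0
  if (any(neg)) {
    stop("effective_length must be positive; offending features: ",
         paste(utils::head(df$feature_id[neg], 5), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("te_annotation", "data.frame")
  df
}

#' TE type to class map of an annotation
#'
#' @param ann a `te_annotation`.
#' @return named character vector: `te_type -> te_class`.
#' @export
te_parent_map <- function(ann) {
  tmap <- unique(ann[ann$kind == "repeat", c("te_type", "te_class")])
  stats::setNames(tmap$te_class, tmap$te_type)
}

#' Default TE taxonomy shipped with the package
#'
#' A minimal two-level taxonomy (type within class) covering the canonical TE
#' types most relevant to leukemia TE-expression analyses: Alu and MIR
#' (SINE); L1 and L2 (LINE); ERV1, ERV3, ERVK, ERVL, generic Endogenous
#' Retrovirus and LTR Retrotransposon (LTR); SAT (Satellite). The canonical
#' repeat taxonomy in routine use has 68 types; this shipped table is a
#' stand-in covering the types this package's analyses and simulations name,
#' and users may supply their own full table wherever a taxonomy is accepted.
#'
#' @return data.frame with columns `te_type`, `te_class`.
#' @export
default_te_taxonomy <- function() {
  path <- system.file("extdata", "te_taxonomy.tsv", package = "teexpr",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  df
}

#' Sample metadata table
#'
#' Validates a sample metadata table: one row per sample with its group label
#' (e.g. pHSC / LSC / Blast cell fractions, or low / high risk) and an
#' optional patient ID used as the pairing key in paired contrasts.
#'
#' @param df data.frame with columns `sample_id`, `group`, and optionally
#'   `patient_id` (empty string = unpaired sample).
#' @return validated data.frame with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (is.null(df$patient_id)) df$patient_id <- ""
  df <- df[c("sample_id", "group", "patient_id")]
  for (col in names(df)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample IDs in metadata: ", paste(dup, collapse = ", "))
  has_pat <- nzchar(df$patient_id)
  key <- paste(df$patient_id[has_pat], df$group[has_pat], sep = "\r")
  dup_pair <- unique(key[duplicated(key)])
  if (length(dup_pair)) {
    stop("each (patient_id, group) pair may occur at most once; duplicated: ",
         paste(gsub("\r", "/", dup_pair), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Features of an expression matrix absent from an annotation
#'
#' Downstream analyses never drop features silently: this reports which
#' features of `x` have no annotation row. Unannotated features are retained
#' for coding-gene analyses but excluded from TE aggregation.
#'
#' @param x an `expr_matrix`.
#' @param ann a `te_annotation`.
#' @return character vector of unannotated feature IDs (possibly empty).
#' @export
unannotated_features <- function(x, ann) {
  setdiff(feature_ids(x), ann$feature_id)
}
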