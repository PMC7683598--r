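#' Default phrase configuration for coregulator polarity
#'
#' Term labels are matched case-insensitively against these substring lists to
#' decide whether an annotation record is evidence of positive or negative
#' control of transcription.  "positive"/"coactivator" phrases count as
#' positive evidence; "negative"/"corepressor" phrases as negative evidence.
#'
#' @return A named list with character vectors `positive`, `negative`,
#'   `coactivator`, `corepressor`.
#' @export
default_phrase_config <- function() {
  list(
    positive    = c("positive control of transcription",
                    "positive regulation of transcription"),
    negative    = c("negative control of transcription",
                    "negative regulation of transcription"),
    coactivator = c("co-activator", "coactivator"),
    corepressor = c("co-repressor", "corepressor")
  )
}

#' Build a canonical transcription-factor list
#'
#' @param genes Character vector of gene symbols (upper-cased on input).
#' @param source Label recording where the list came from, e.g. a curated
#'   proteome database or a large-scale annotation project.
#' @return An object of class `tf_list`.
#' @export
tf_list <- function(genes, source = "canonical_a") {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("TF list must be non-empty")
  structure(list(source = source, genes = genes), class = "tf_list")
}

# resolve each annotation record to a polarity; errors name offending records
.resolve_polarity <- function(ann, phrase_config) {
  valid <- c("positive", "negative", "coactivator", "corepressor")
  if ("polarity" %in% names(ann) && !all(is.na(ann$polarity))) {
    pol <- as.character(ann$polarity)
    bad <- which(!(pol %in% valid) | is.na(pol))
    if (length(bad)) {
      stop("unknown polarity for record(s): ",
           paste(sprintf("%s/%s ('%s')", ann$gene[bad], ann$term_id[bad],
                         pol[bad]), collapse = ", "))
    }
    return(pol)
  }
  lab <- tolower(as.character(ann$term_label))
  pol <- rep(NA_character_, nrow(ann))
  for (p in valid) {
    hits <- Reduce(`|`, lapply(tolower(phrase_config[[p]]),
                               function(ph) grepl(ph, lab, fixed = TRUE)),
                   accumulate = FALSE)
    pol[is.na(pol) & hits] <- p
  }
  bad <- which(is.na(pol))
  if (length(bad)) {
    stop("unknown polarity (no phrase match) for record(s): ",
         paste(sprintf("%s/%s ('%s')", ann$gene[bad], ann$term_id[bad],
                       ann$term_label[bad]), collapse = ", "))
  }
  pol
}

#' Classify genes into mutually exclusive regulator classes
#'
#' Builds a disjoint gene-class catalog from ontology-style annotation
#' records and canonical TF lists.  Precedence is TF > MIXED > COA/COR: a
#' gene on any canonical TF list is a TF regardless of coregulator evidence;
#' of the remainder, genes with both positive and negative evidence are
#' MIXED, genes with exclusively positive evidence are coactivators (COA)
#' and genes with exclusively negative evidence are corepressors (COR).
#' Genes with no evidence at all are left unassigned.
#'
#' @param annotations Data frame with columns `gene`, `term_id`,
#'   `term_label` and optionally `polarity` (one of positive, negative,
#'   coactivator, corepressor).  When `polarity` is absent it is derived by
#'   case-insensitive substring matching of `term_label` against
#'   `phrase_config`.
#' @param tf_lists A single `tf_list` or a list of them.
#' @param phrase_config Phrase lists, see [default_phrase_config()].
#' @return A `gene_class_catalog`: list with `assignment` (data frame of
#'   gene, class, provenance), `counts` (named integer vector) and the
#'   phrase configuration used.
#' @export
classify_genes <- function(annotations, tf_lists = list(),
                           phrase_config = default_phrase_config()) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("annotation table is empty")
  }
  stopifnot(all(c("gene", "term_id", "term_label") %in% names(annotations)))
  ann <- annotations
  ann$gene <- toupper(as.character(ann$gene))
  if (any(!nzchar(ann$gene))) stop("empty gene symbol in annotation table")
  # duplicate (gene, term) pairs collapse to one record
  ann <- ann[!duplicated(ann[, c("gene", "term_id")]), , drop = FALSE]
  ann$polarity <- .resolve_polarity(ann, phrase_config)
  ann$evidence <- ifelse(ann$polarity %in% c("positive", "coactivator"),
                         "positive", "negative")

  if (inherits(tf_lists, "tf_list")) tf_lists <- list(tf_lists)
  tf_genes <- unique(toupper(unlist(lapply(tf_lists, `[[`, "genes"))))

  pos_genes <- unique(ann$gene[ann$evidence == "positive"])
  neg_genes <- unique(ann$gene[ann$evidence == "negative"])

  all_genes <- sort(unique(c(tf_genes, pos_genes, neg_genes)))
  cls <- character(length(all_genes))
  names(cls) <- all_genes
  cls[all_genes %in% pos_genes & all_genes %in% neg_genes] <- "MIXED"
  cls[all_genes %in% pos_genes & !(all_genes %in% neg_genes)] <- "COA"
  cls[!(all_genes %in% pos_genes) & all_genes %in% neg_genes] <- "COR"
  cls[all_genes %in% tf_genes] <- "TF"   # TF precedence last, overrides

  prov <- vapply(all_genes, function(g) {
    src <- character(0)
    for (tl in tf_lists) if (g %in% tl$genes) src <- c(src, tl$source)
    terms <- sort(unique(ann$term_id[ann$gene == g]))
    paste(c(src, terms), collapse = ";")
  }, character(1))

  assignment <- data.frame(gene = all_genes, class = unname(cls),
                           provenance = unname(prov),
                           stringsAsFactors = FALSE)
  new_gene_class_catalog(assignment, phrase_config)
}

new_gene_class_catalog <- function(assignment, phrase_config = NULL) {
  counts <- table(factor(assignment$class,
                         levels = c("TF", "COA", "COR", "MIXED")))
  structure(list(assignment = assignment,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 phrase_config = phrase_config),
            class = "gene_class_catalog")
}

#' @export
print.gene_class_catalog <- function(x, ...) {
  cat("gene_class_catalog:", nrow(x$assignment), "genes\n")
  print(x$counts)
  invisible(x)
}

#' Genes belonging to one class of a catalog
#'
#' @param catalog A `gene_class_catalog`.
#' @param class One of "TF", "COA", "COR", "MIXED".
#' @return Character vector of gene symbols.
#' @export
class_genes <- function(catalog, class) {
  stopifnot(inherits(catalog, "gene_class_catalog"))
  catalog$assignment$gene[catalog$assignment$class == class]
}

#' Restrict a catalog to the genes detected in a cohort
#'
#' Class tests compare each family against the genes actually detected in a
#' given cohort, so the catalog is intersected with the cohort's detected
#' gene set and per-class counts recomputed.
#'
#' @param catalog A `gene_class_catalog`.
#' @param detected_genes Character vector of detected gene symbols.
#' @return A restricted `gene_class_catalog`.
#' @export
restrict_to_detected <- function(catalog, detected_genes) {
  stopifnot(inherits(catalog, "gene_class_catalog"))
  if (length(detected_genes) == 0L) stop("detected gene set is empty")
  detected_genes <- toupper(as.character(detected_genes))
  keep <- toupper(catalog$assignment$gene) %in% detected_genes
  if (!any(keep)) {
    stop("no catalog gene detected in the cohort; cohort unusable")
  }
  new_gene_class_catalog(catalog$assignment[keep, , drop = FALSE],
                         catalog$phrase_config)
}

#' Read an annotation table or TF list from TSV
#'
#' Annotation TSVs carry columns gene, term_id, term_label and optionally
#' polarity; TF-list TSVs carry a single `gene` column (or one symbol per
#' line without a header when `header = FALSE`).
#'
#' @param path File path.
#' @param header Logical, whether the file has a header line.
#' @return A data frame.
#' @export
read_annotation_tsv <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, stringsAsFactors = FALSE)
}

#' Write a gene-class catalog as TSV
#'
#' @param catalog A `gene_class_catalog`.
#' @param path Output file path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_class_catalog"))
  utils::write.table(catalog$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
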