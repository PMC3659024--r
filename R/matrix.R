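#' Construct a relationship matrix
#'
#' @param values symmetric numeric matrix.
#' @param ids character vector of ids (defaults to rownames of `values`).
#' @return a [RelationshipMatrix].
#' @export
relationshipMatrix <- function(values, ids = rownames(values)) {
  if (is.null(ids)) stopf("ids are required (or set rownames on values)")
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", ids = as.character(ids), values = values)
}

#' @describeIn ids ids indexing a relationship matrix.
#' @export
setMethod("ids", "RelationshipMatrix", function(x) x@ids)

#' @describeIn nIndividuals dimension of a relationship matrix.
#' @export
setMethod("nIndividuals", "RelationshipMatrix", function(x) length(x@ids))

#' @export
setMethod("dim", "RelationshipMatrix", function(x) dim(x@values))

#' Dense matrix values of a RelationshipMatrix
#' @param x a [RelationshipMatrix].
#' @param ... unused.
#' @return base numeric matrix with ids as dimnames.
#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

#' Subset a relationship matrix to (and reorder by) a set of ids
#' @param x a [RelationshipMatrix].
#' @param ids character vector, subset of `ids(x)`.
#' @return a [RelationshipMatrix] over `ids` in the given order.
#' @export
subsetMatrix <- function(x, ids) {
  missing <- setdiff(ids, x@ids)
  if (length(missing))
    stopf("ids absent from matrix: %s", paste(missing, collapse = ", "))
  relationshipMatrix(x@values[ids, ids, drop = FALSE], ids)
}

setMethod("show", "RelationshipMatrix", function(object) {
  n <- length(object@ids)
  cat("RelationshipMatrix over", n, "individuals\n")
  k <- min(n, 5L)
  if (k) print(round(object@values[seq_len(k), seq_len(k), drop = FALSE], 4))
  if (n > k) cat("...\n")
  invisible(object)
})

# Cholesky with an explicit diagonal stabilization offset: if plain chol()
# fails, retry with +eps I and report the offset used.
cholPSD <- function(M, eps = 1e-8) {
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(L)) return(list(R = L, offset = 0))
  L <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
  if (is.null(L))
    stopf("matrix is not positive semidefinite within the %g offset", eps)
  list(R = L, offset = eps)
}

#' Stabilize a relationship matrix to positive definiteness
#'
#' Attempts a Cholesky factorization; on failure adds `eps` to the diagonal
#' (and messages the offset).  Relationship matrices built from valid
#' pedigrees are positive semidefinite by construction, but derived or
#' normalized matrices can sit numerically on the boundary.
#'
#' @param x a [RelationshipMatrix].
#' @param eps diagonal offset used when plain Cholesky fails (default 1e-8).
#' @return `x`, possibly with `eps` added to its diagonal.
#' @export
stabilizePSD <- function(x, eps = 1e-8) {
  f <- cholPSD(x@values, eps)
  if (f$offset > 0) {
    message("relationship matrix stabilized with +", format(eps), " I")
    return(relationshipMatrix(x@values + diag(eps, nrow(x@values)), x@ids))
  }
  x
}

#' Write a relationship matrix
#'
#' `"dense"` writes the full matrix with an `id` first column and ids as the
#' header; `"triplet"` writes the sparse lower triangle as
#' `(id_i, id_j, value)` rows with `j <= i`, keeping all diagonal entries
#' and only nonzero off-diagonals.
#'
#' @param x a [RelationshipMatrix].
#' @param path output path.
#' @param format `"dense"` or `"triplet"`.
#' @param sep field separator.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeRelationshipMatrix <- function(x, path, format = c("dense", "triplet"),
                                    sep = ",", header = character(0)) {
  format <- match.arg(format)
  V <- x@values
  if (format == "dense") {
    df <- data.frame(id = x@ids, V, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("id", x@ids)
    writeDelimited(df, path, sep = sep, header = header)
  } else {
    lower <- which(lower.tri(V, diag = TRUE), arr.ind = TRUE)
    keep <- lower[V[lower] != 0 | lower[, 1] == lower[, 2], , drop = FALSE]
    df <- data.frame(id_i = x@ids[keep[, 1]], id_j = x@ids[keep[, 2]],
                     value = V[keep], stringsAsFactors = FALSE)
    writeDelimited(df, path, sep = sep, header = header)
  }
}

#' Read a relationship matrix written by [writeRelationshipMatrix()]
#'
#' The format is autodetected from the columns: a `value` column means
#' triplet, otherwise dense.
#'
#' @param path input path.
#' @return a [RelationshipMatrix].
#' @export
readRelationshipMatrix <- function(path) {
  df <- readDelimited(path)
  if (all(c("id_i", "id_j", "value") %in% names(df))) {
    idset <- unique(c(df$id_i, df$id_j))
    n <- length(idset)
    V <- matrix(0, n, n, dimnames = list(idset, idset))
    V[cbind(df$id_i, df$id_j)] <- as.numeric(df$value)
    V[cbind(df$id_j, df$id_i)] <- as.numeric(df$value)
    relationshipMatrix(V, idset)
  } else {
    idset <- as.character(df[[1]])
    V <- as.matrix(df[, -1, drop = FALSE])
    mode(V) <- "numeric"
    relationshipMatrix(V, idset)
  }
}

# Delimited-text plumbing shared by all readers/writers.  Comma or tab is
# autodetected from the first non-comment line; '#' lines are provenance.
readDelimited <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("file %s has no data rows", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  utils::read.table(text = lines, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

writeDelimited <- function(df, path, sep = ",", header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
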