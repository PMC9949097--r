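#' @include AllClasses.R
NULL

## Schema registry: column names, types, and per-table validation rules.
.tableSchemas <- list(
    measurements = list(
        columns = c(receptor = "character", valency = "numeric",
                    igg_a = "character", igg_b = "character",
                    frac_a = "numeric", replicate = "character",
                    rfu = "numeric"),
        check = function(d) {
            err <- character()
            if (nrow(d)) {
                if (any(d$rfu < 0, na.rm = TRUE)) err <- c(err, "rfu must be >= 0")
                if (any(d$frac_a < 0 | d$frac_a > 1, na.rm = TRUE))
                    err <- c(err, "frac_a must lie in [0, 1]")
            }
            err
        }),
    receptor_expression = list(
        columns = c(receptor = "character", replicate = "character",
                    sites_per_cell = "numeric"),
        check = function(d) {
            if (nrow(d) && any(d$sites_per_cell <= 0, na.rm = TRUE))
                "sites_per_cell must be > 0" else character()
        }),
    effector_profiles = list(
        columns = c(cell_type = "character", receptor = "character",
                    sites_per_cell = "numeric"),
        check = function(d) {
            if (nrow(d) && any(d$sites_per_cell < 0, na.rm = TRUE))
                "sites_per_cell must be >= 0" else character()
        }),
    depletion = list(
        columns = c(condition = "character", donor = "character",
                    replicate = "character",
                    depletion_fraction = "numeric"),
        check = function(d) character()),
    posterior_summary = list(
        columns = c(parameter = "character", median = "numeric",
                    q25 = "numeric", q75 = "numeric", ess = "numeric",
                    rhat = "numeric"),
        check = function(d) character())
)

#' Registered table schemas
#' @return Character vector of schema identifiers accepted by
#'   [readTable()] and [writeTable()].
#' @export
tableSchemas <- function() names(.tableSchemas)

.coerceSchema <- function(data, schemaId) {
    sch <- .tableSchemas[[schemaId]]
    if (is.null(sch)) stop("unknown schema '", schemaId, "'; known: ",
                           paste(names(.tableSchemas), collapse = ", "))
    cols <- sch$columns
    problems <- character()
    missing <- setdiff(names(cols), names(data))
    if (length(missing))
        problems <- c(problems, paste0("missing column(s): ",
                                       paste(missing, collapse = ", ")))
    extra <- setdiff(names(data), names(cols))
    if (length(extra))
        problems <- c(problems, paste0("unknown column(s): ",
                                       paste(extra, collapse = ", ")))
    if (!length(problems)) {
        for (nm in names(cols)) {
            if (cols[[nm]] == "numeric") {
                v <- data[[nm]]
                if (is.character(v) || is.factor(v)) {
                    suppressWarnings(v2 <- as.numeric(as.character(v)))
                    if (any(is.na(v2) & !is.na(v)))
                        problems <- c(problems,
                                      paste0("column ", nm, " is not numeric"))
                    else data[[nm]] <- v2
                } else data[[nm]] <- as.numeric(v)
            } else {
                data[[nm]] <- as.character(data[[nm]])
            }
        }
    }
    if (!length(problems)) problems <- sch$check(data)
    if (length(problems))
        stop("schema '", schemaId, "' validation failed:\n  - ",
             paste(problems, collapse = "\n  - "))
    data[, names(cols), drop = FALSE]
}

#' Read / write a schema-validated CSV table
#'
#' CSV is the package's single interchange format. Reading validates the
#' header and column types strictly against the registered schema
#' (see [tableSchemas()]) and reports every violation; an empty table with
#' the right header is valid. Writing emits plain CSV without row names so
#' that a write/read round trip is lossless for finite values.
#'
#' @param path CSV file path.
#' @param schemaId one of [tableSchemas()].
#' @param data data.frame to write (validated before writing).
#' @return \code{readTable}: validated data.frame; \code{writeTable}: the
#'   path, invisibly.
#' @export
readTable <- function(path, schemaId) {
    if (!file.exists(path)) stop("input file not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
    .coerceSchema(d, schemaId)
}

#' @rdname readTable
#' @export
writeTable <- function(data, path, schemaId) {
    d <- .coerceSchema(as.data.frame(data), schemaId)
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}

#' Read / write an affinity matrix CSV
#'
#' Affinity tables are CSVs with IgG species in rows (first column
#' \code{ligand}) and receptor species in columns; entries are association
#' constants in M^-1, with zero or empty meaning documented non-binding.
#' The companion standard-error table uses the identical shape.
#'
#' @param path CSV file path.
#' @param x an [AffinityMatrix-class] (or matrix of standard errors with
#'   dimnames) to write.
#' @return \code{readAffinityCsv}: an [AffinityMatrix-class];
#'   \code{writeAffinityCsv}: the path, invisibly.
#' @export
readAffinityCsv <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1L] != "ligand")
        stop("affinity CSV must have 'ligand' as its first column")
    m <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("affinity CSV entries must be numeric")
    m[is.na(m)] <- 0      # absent = documented non-binding
    if (any(m < 0)) stop("affinity CSV contains negative entries")
    rownames(m) <- d$ligand
    affinityMatrix(m)
}

#' @rdname readAffinityCsv
#' @export
writeAffinityCsv <- function(x, path) {
    m <- if (is(x, "AffinityMatrix")) x@.Data else as.matrix(x)
    d <- data.frame(ligand = rownames(m), m, check.names = FALSE)
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}

#' Receptor-expression replicate lists from a long table
#'
#' @param data a \code{receptor_expression} table (see [readTable()]).
#' @return Named list of numeric vectors, one per receptor, suitable for
#'   [buildReceptorPriors()].
#' @export
receptorExpressionList <- function(data) {
    split(data$sites_per_cell, data$receptor)
}
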