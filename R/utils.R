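# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-stage seed fan-out from one global seed. Keeps every
# derived seed a valid 32-bit integer and distinct across stages.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    inventory = 101L, segments = 211L, landscape = 307L,
    clustering = 401L, model = 503L, rfe = 601L, importance = 701L,
    folds = 809L, generic = 907L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else offsets[["generic"]]
  as.integer((as.numeric(seed) * 2654435761 + off) %% 2100000000)
}

# Run `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Coerce a wide site-by-species tibble (id column + numeric species columns)
# to a base matrix with site rownames. Accepts a matrix unchanged.
as_species_matrix <- function(x, id_col = "plot_id") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!id_col %in% names(x)) {
    abort(paste0("column `", id_col, "` not found in species table"))
  }
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (!is.numeric(m)) abort("species columns must be numeric abundances")
  rownames(m) <- ids
  m
}

# Validate a square symmetric dissimilarity matrix in [0, 1].
check_dissim <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- seq_len(nrow(D))
  }
  if (max(abs(D - t(D))) > 1e-8) abort("dissimilarity matrix must be symmetric")
  if (any(D < -1e-12) || any(D > 1 + 1e-12)) {
    abort("dissimilarity values must lie in [0, 1]")
  }
  D
}

# Align a label vector (named, or a tibble with site/cluster columns) with
# the rownames of a matrix; returns an integer-ish vector named by site.
align_labels <- function(labels, site_ids) {
  if (is.data.frame(labels)) {
    id_col <- intersect(c("site_id", "plot_id", "segment_id"), names(labels))[1]
    cl_col <- intersect(c("cluster_id", "cluster", "label"), names(labels))[1]
    if (is.na(id_col) || is.na(cl_col)) {
      abort("label table needs a site/plot id column and a cluster column")
    }
    labels <- setNames(labels[[cl_col]], as.character(labels[[id_col]]))
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(site_ids)) {
      abort("unnamed labels must match the number of sites")
    }
    names(labels) <- site_ids
  }
  missing <- setdiff(site_ids, names(labels))
  if (length(missing) > 0) {
    abort(paste0("no cluster label for site(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  labels[site_ids]
}
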