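#' Observation schema for lineage phenotypes
#'
#' Lineage observations come in two flavours: phase-specific measurements
#' (G1 and S/G2 fate + duration per cell, as tracked for AU565 cells) or a
#' single whole-lifetime fate + duration (as for MCF10A cells). The schema
#' records which one a population uses; lifetime data occupy only the
#' `*_g1` observation slots.
#'
#' @param mode `"phase_specific"` (two phases per cell) or `"lifetime"`
#'   (one observation per cell).
#' @return An object of class `obs_schema` with fields `mode` and `n_phases`.
#' @export
#' @examples
#' obs_schema("lifetime")$n_phases
obs_schema <- function(mode = c("phase_specific", "lifetime")) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, n_phases = if (mode == "phase_specific") 2L else 1L),
    class = "obs_schema"
  )
}

#' @export
print.obs_schema <- function(x, ...) {
  cat("<obs_schema> mode:", x$mode, "(", x$n_phases, "phase(s) )\n")
  invisible(x)
}

OBS_COLS <- c("fate_g1", "dur_g1", "cens_g1",
              "fate_g2", "dur_g2", "cens_g2",
              "observed", "true_state")

# Canonical per-cell observation frame; missing columns filled with NA,
# types coerced. `observed` defaults to TRUE.
normalize_obs <- function(records, n) {
  obs <- data.frame(
    fate_g1 = rep(NA_real_, n), dur_g1 = rep(NA_real_, n),
    cens_g1 = rep(NA_integer_, n),
    fate_g2 = rep(NA_real_, n), dur_g2 = rep(NA_real_, n),
    cens_g2 = rep(NA_integer_, n),
    observed = rep(TRUE, n), true_state = rep(NA_integer_, n)
  )
  for (cc in OBS_COLS) {
    if (cc %in% names(records)) {
      v <- records[[cc]]
      obs[[cc]] <- switch(cc,
        observed = as.logical(v),
        true_state = as.integer(v),
        cens_g1 = , cens_g2 = as.integer(v),
        as.numeric(v)
      )
    }
  }
  obs$observed[is.na(obs$observed)] <- TRUE
  obs
}

check_obs_values <- function(obs, where = "records") {
  for (ph in c("g1", "g2")) {
    fate <- obs[[paste0("fate_", ph)]]
    bad <- which(!is.na(fate) & !(fate %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("%s row %d: non-binary fate_%s value %s",
                   where, bad[1], ph, fate[bad[1]]), call. = FALSE)
    }
    dur <- obs[[paste0("dur_", ph)]]
    bad <- which(!is.na(dur) & dur < 0)
    if (length(bad)) {
      stop(sprintf("%s row %d: negative dur_%s value %s",
                   where, bad[1], ph, dur[bad[1]]), call. = FALSE)
    }
    cens <- obs[[paste0("cens_", ph)]]
    bad <- which(!is.na(cens) & !(cens %in% c(0L, 1L)))
    if (length(bad)) {
      stop(sprintf("%s row %d: cens_%s must be 0 or 1", where, bad[1], ph),
           call. = FALSE)
    }
  }
  # an unobserved placeholder carries no data at all
  unob <- which(!obs$observed)
  if (length(unob)) {
    has_data <- !is.na(obs$fate_g1[unob]) | !is.na(obs$dur_g1[unob]) |
      !is.na(obs$fate_g2[unob]) | !is.na(obs$dur_g2[unob])
    if (any(has_data)) {
      stop(sprintf("%s row %d: unobserved cell carries observation values",
                   where, unob[which(has_data)[1]]), call. = FALSE)
    }
  }
  invisible(obs)
}

new_lineage_tree <- function(cell_id, parent, daughters, generation, obs,
                             condition, lineage_id) {
  structure(
    list(cell_id = cell_id, parent = parent, daughters = daughters,
         generation = generation, obs = obs,
         condition = condition, lineage_id = lineage_id),
    class = "lineage_tree"
  )
}

#' Build a validated lineage tree from per-cell rows
#'
#' Assembles a binary genealogical tree from a table with one row per cell.
#' Exactly one row must be a root (empty/NA `parent_id`); every other row's
#' `parent_id` must name another row, and every cell must have 0 or 2
#' daughters. Cells are reordered breadth-first from the root and
#' generations are computed (root = generation 1).
#'
#' @param records Data frame with columns `cell_id`, `parent_id` and any of
#'   `fate_g1`, `dur_g1`, `cens_g1`, `fate_g2`, `dur_g2`, `cens_g2`,
#'   `observed`, `true_state`.
#' @param condition Condition label attached to the lineage.
#' @param lineage_id Lineage label.
#' @return A `lineage_tree`: breadth-first ordered cells with `parent` /
#'   `daughters` position links, `generation`, and an observation frame.
#' @export
#' @examples
#' tr <- build_lineage(data.frame(cell_id = 0, parent_id = NA))
#' n_cells(tr)
build_lineage <- function(records, condition = "control",
                          lineage_id = "lineage-1") {
  stopifnot(is.data.frame(records))
  need <- c("cell_id", "parent_id")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0) stop("records contains no cells", call. = FALSE)
  ids <- as.character(records$cell_id)
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id: ", ids[anyDuplicated(ids)], call. = FALSE)
  }
  pid <- as.character(records$parent_id)
  pid[!is.na(pid) & pid == ""] <- NA_character_
  is_root <- is.na(pid)
  if (sum(is_root) != 1) {
    stop(sprintf("expected exactly one root cell, found %d", sum(is_root)),
         call. = FALSE)
  }
  ppos <- match(pid, ids)
  bad <- which(!is_root & is.na(ppos))
  if (length(bad)) {
    stop(sprintf("cell %s references parent %s which matches no row",
                 ids[bad[1]], pid[bad[1]]), call. = FALSE)
  }
  ndaughters <- tabulate(ppos[!is_root], nbins = n)
  badd <- which(!(ndaughters %in% c(0L, 2L)))
  if (length(badd)) {
    stop(sprintf("cell %s has %d daughter(s); lineage trees are binary (0 or 2)",
                 ids[badd[1]], ndaughters[badd[1]]), call. = FALSE)
  }

  kids <- vector("list", n)
  for (i in which(!is_root)) kids[[ppos[i]]] <- c(kids[[ppos[i]]], i)

  # breadth-first ordering from the root; a cycle leaves cells unvisited
  ord <- integer(n)
  gen <- integer(n)
  root <- which(is_root)
  ord[1] <- root
  gen[root] <- 1L
  head_i <- 1L; tail_i <- 1L
  while (head_i <= tail_i) {
    cur <- ord[head_i]
    for (ch in kids[[cur]]) {
      tail_i <- tail_i + 1L
      ord[tail_i] <- ch
      gen[ch] <- gen[cur] + 1L
    }
    head_i <- head_i + 1L
  }
  if (tail_i != n) {
    stop("lineage contains cells unreachable from the root (cycle or orphan subtree)",
         call. = FALSE)
  }

  newpos <- integer(n); newpos[ord] <- seq_len(n)
  parent <- ifelse(is.na(ppos[ord]), NA_integer_, newpos[ppos[ord]])
  daughters <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) {
      p <- parent[i]
      slot <- if (is.na(daughters[p, 1])) 1L else 2L
      daughters[p, slot] <- i
    }
  }
  obs <- normalize_obs(records[ord, , drop = FALSE], n)
  rownames(obs) <- NULL
  check_obs_values(obs)
  new_lineage_tree(ids[ord], as.integer(parent), daughters, gen[ord], obs,
                   condition, lineage_id)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %s | condition %s | %d cells (%d observed), %d generation(s)\n",
              x$lineage_id, x$condition, n_cells(x), sum(x$obs$observed),
              max(x$generation)))
  invisible(x)
}

#' Number of cells in a tree or population
#' @param x A `lineage_tree` or `lineage_population`.
#' @param observed_only Count only observed cells?
#' @return Integer cell count.
#' @export
n_cells <- function(x, observed_only = FALSE) {
  if (inherits(x, "lineage_population")) {
    return(sum(vapply(x$lineages, n_cells, integer(1),
                      observed_only = observed_only)))
  }
  if (observed_only) sum(x$obs$observed) else length(x$cell_id)
}

#' Leaf cells of a lineage tree
#'
#' @param tree A `lineage_tree`.
#' @return Integer positions (1-based, breadth-first order) of cells with no
#'   daughters.
#' @export
leaves <- function(tree) {
  which(is.na(tree$daughters[, 1]))
}

#' Root cells of a population
#'
#' @param population A `lineage_population`.
#' @return Data frame with `lineage_id` and `cell_id` of each generation-1
#'   cell (one per lineage).
#' @export
roots <- function(population) {
  data.frame(
    lineage_id = vapply(population$lineages, `[[`, "", "lineage_id"),
    cell_id = vapply(population$lineages,
                     function(tr) as.character(tr$cell_id[1]), "")
  )
}

#' Assemble a population of lineage trees
#'
#' @param lineages List of `lineage_tree` objects.
#' @param schema An [obs_schema()]. All lineages must conform.
#' @param conditions Ordered character vector of condition labels; the order
#'   encodes dose order for scale-ordered fits. Defaults to the distinct
#'   conditions in order of first appearance.
#' @return A `lineage_population`.
#' @export
lineage_population <- function(lineages, schema = obs_schema("phase_specific"),
                               conditions = NULL) {
  stopifnot(is.list(lineages))
  for (tr in lineages) {
    if (!inherits(tr, "lineage_tree")) stop("lineages must be lineage_tree objects")
  }
  conds <- vapply(lineages, `[[`, "", "condition")
  if (is.null(conditions)) conditions <- unique(conds)
  if (length(lineages) && !all(conds %in% conditions)) {
    stop("lineage condition(s) not listed in conditions: ",
         paste(setdiff(conds, conditions), collapse = ", "))
  }
  ids <- vapply(lineages, `[[`, "", "lineage_id")
  if (anyDuplicated(ids)) stop("duplicate lineage_id: ", ids[anyDuplicated(ids)])
  structure(list(lineages = lineages, conditions = conditions, schema = schema),
            class = "lineage_population")
}

#' @export
print.lineage_population <- function(x, ...) {
  cat(sprintf("<lineage_population> %d lineage(s), %d cells (%d observed), schema %s\n",
              length(x$lineages), n_cells(x), n_cells(x, observed_only = TRUE),
              x$schema$mode))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

# per-cell rows in the canonical column order (used by CSV writer and by
# build_lineage idempotency)
as_records <- function(tree) {
  n <- n_cells(tree)
  data.frame(
    lineage_id = rep(tree$lineage_id, n),
    cell_id = tree$cell_id,
    parent_id = ifelse(is.na(tree$parent), NA, tree$cell_id[tree$parent]),
    condition = rep(tree$condition, n),
    tree$obs
  )
}

#' Read / write populations in the canonical CSV schema
#'
#' One row per cell with columns `lineage_id, cell_id, parent_id` (empty for
#' roots), `condition`, `fate_g1, dur_g1, cens_g1`, `fate_g2, dur_g2,
#' cens_g2` (phase-specific schema only), `observed` (0/1) and optional
#' `true_state`. Missing values are empty fields, never sentinels.
#' `read_population_csv(write_population_csv(p, f), schema)` is the identity
#' on populations up to row order.
#'
#' @param path CSV file path.
#' @param schema An [obs_schema()] describing the file.
#' @param conditions Optional condition order (dose order); defaults to
#'   order of first appearance in the file.
#' @return `read_population_csv` returns a `lineage_population`;
#'   `write_population_csv` returns `path` invisibly.
#' @export
read_population_csv <- function(path, schema = obs_schema("phase_specific"),
                                conditions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lineage_id = "character",
                                       cell_id = "character",
                                       parent_id = "character"))
  need <- c("lineage_id", "cell_id", "parent_id", "condition",
            "fate_g1", "dur_g1", "cens_g1", "observed")
  if (schema$mode == "phase_specific") {
    need <- c(need, "fate_g2", "dur_g2", "cens_g2")
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(lineage_population(list(), schema,
                              conditions = conditions %||% character(0)))
  }
  check_obs_values(normalize_obs(df, nrow(df)), where = basename(path))
  lineages <- lapply(split(seq_len(nrow(df)), df$lineage_id), function(idx) {
    sub <- df[idx, , drop = FALSE]
    build_lineage(sub, condition = sub$condition[1],
                  lineage_id = sub$lineage_id[1])
  })
  if (is.null(conditions)) conditions <- unique(df$condition)
  # keep file order of lineages
  first_row <- vapply(split(seq_len(nrow(df)), df$lineage_id), min, 0)
  lineages <- lineages[order(first_row)]
  names(lineages) <- NULL
  lineage_population(lineages, schema, conditions = conditions)
}

#' @rdname read_population_csv
#' @param population A `lineage_population` to serialize.
#' @export
write_population_csv <- function(population, path) {
  rows <- lapply(population$lineages, as_records)
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)),
                    c("lineage_id", "cell_id", "parent_id", "condition", OBS_COLS))
  if (population$schema$mode == "lifetime") {
    df <- df[, setdiff(names(df), c("fate_g2", "dur_g2", "cens_g2")),
             drop = FALSE]
  }
  if (nrow(df) && all(is.na(df$true_state))) df$true_state <- NULL
  df$observed <- as.integer(df$observed)
  # full-precision serialization so numeric fields round-trip bit-exactly
  for (cc in intersect(c("dur_g1", "dur_g2"), names(df))) {
    v <- df[[cc]]
    df[[cc]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
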