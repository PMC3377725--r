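# Loop-design containers and tabular I/O.
#
# A loop design is a directed multigraph: nodes are hybridization units
# (one RNA pool each), and every array is an arrow tail -> head, meaning the
# tail sample was labeled in the numerator channel.  The normalized log
# ratio of array a is modelled as M_a = gamma + lambda_tail - lambda_head + eps.

#' Construct a loop design
#'
#' Bundles the hybridization units, the arrays (directed sample pairs with
#' dye assignment), and optional group declarations into a validated
#' `loop_design` object.
#'
#' @param units data frame with columns `unit_id`, `individual`, and
#'   optionally `section` and `tech_rep` (empty string or `NA` when unset).
#'   A unit with `tech_rep` set must also have `section` set.
#' @param arrays data frame with columns `array_id`, `tail`, `head`; an
#'   array `tail -> head` co-hybridizes the two units, tail in the numerator
#'   channel, so its expected log ratio is `gamma + lambda[tail] - lambda[head]`.
#' @param groups named list of character vectors of sample labels (e.g.
#'   `G1`, `G2`, `G3`). Labels may be unit ids or composite labels declared
#'   in a sample hierarchy.
#' @return An object of class `loop_design` with elements `units`, `arrays`,
#'   `groups` and `n_arrows`.
#' @seealso [read_loop_design()], [validate_design()], [fig1_design()]
#' @export
loop_design <- function(units, arrays, groups = list()) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  arrays <- as.data.frame(arrays, stringsAsFactors = FALSE)
  need_u <- c("unit_id", "individual")
  if (!all(need_u %in% names(units)))
    stop("units must have columns: ", paste(need_u, collapse = ", "))
  if (is.null(units$section)) units$section <- NA_character_
  if (is.null(units$tech_rep)) units$tech_rep <- NA_character_
  for (col in c("unit_id", "individual", "section", "tech_rep")) {
    units[[col]] <- as.character(units[[col]])
    units[[col]][!is.na(units[[col]]) & units[[col]] == ""] <- NA_character_
  }
  need_a <- c("array_id", "tail", "head")
  if (!all(need_a %in% names(arrays)))
    stop("arrays must have columns: ", paste(need_a, collapse = ", "))
  for (col in need_a) arrays[[col]] <- as.character(arrays[[col]])

  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id: ",
         paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "))
  if (anyDuplicated(arrays$array_id))
    stop("duplicate array_id: ",
         paste(unique(arrays$array_id[duplicated(arrays$array_id)]), collapse = ", "))
  bad <- !is.na(units$tech_rep) & is.na(units$section)
  if (any(bad))
    stop("tech_rep set without section for unit(s): ",
         paste(units$unit_id[bad], collapse = ", "))
  unk <- setdiff(c(arrays$tail, arrays$head), units$unit_id)
  if (length(unk))
    stop("array references undeclared unit(s): ", paste(unk, collapse = ", "))
  self <- arrays$tail == arrays$head
  if (any(self))
    stop("array(s) with tail == head: ",
         paste(arrays$array_id[self], collapse = ", "))
  if (length(groups)) {
    if (is.null(names(groups)) || any(names(groups) == ""))
      stop("groups must be a named list")
    groups <- lapply(groups, as.character)
  }
  structure(
    list(units = units, arrays = arrays, groups = groups,
         n_arrows = nrow(arrays)),
    class = "loop_design"
  )
}

#' @export
print.loop_design <- function(x, ...) {
  cat("Loop design:", nrow(x$units), "hybridization units,",
      x$n_arrows, "arrays\n")
  comp <- .components(x)
  cat("  connected components:", max(comp), "\n")
  if (length(x$groups))
    for (g in names(x$groups))
      cat("  ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# component label per unit (undirected graph over arrays), simple BFS
.components <- function(design) {
  ids <- design$units$unit_id
  adj <- lapply(ids, function(u) {
    a <- design$arrays
    unique(c(a$head[a$tail == u], a$tail[a$head == u]))
  })
  names(adj) <- ids
  comp <- setNames(rep(0L, length(ids)), ids)
  k <- 0L
  for (u in ids) {
    if (comp[u] > 0L) next
    k <- k + 1L
    queue <- u
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

#' Construct a sample hierarchy
#'
#' The hierarchy declares composite samples as unweighted means of their
#' children, e.g. a tissue section as the mean of its technical replicates
#' and an individual as the mean of its sections. Children may themselves
#' be composites; leaves must be hybridization units.
#'
#' @param composite_map named list: composite label -> character vector of
#'   child labels.
#' @return An object of class `sample_hierarchy`.
#' @export
sample_hierarchy <- function(composite_map = list()) {
  if (length(composite_map)) {
    if (is.null(names(composite_map)) || any(names(composite_map) == ""))
      stop("composite_map must be a named list")
    composite_map <- lapply(composite_map, as.character)
    # cycle check: repeatedly strip composites all of whose children are resolved
    pending <- names(composite_map)
    resolved <- character(0)
    repeat {
      ready <- pending[vapply(pending, function(cmp) {
        !any(composite_map[[cmp]] %in% pending)
      }, logical(1))]
      if (!length(ready)) break
      resolved <- c(resolved, ready)
      pending <- setdiff(pending, ready)
    }
    if (length(pending))
      stop("cyclic composite definition(s): ", paste(pending, collapse = ", "))
  }
  structure(list(composite_map = composite_map), class = "sample_hierarchy")
}

#' @export
print.sample_hierarchy <- function(x, ...) {
  cat("Sample hierarchy:", length(x$composite_map), "composite label(s)\n")
  for (cmp in names(x$composite_map))
    cat("  ", cmp, " = mean(", paste(x$composite_map[[cmp]], collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

# -- tabular I/O ------------------------------------------------------------

# Strict TSV reader: header line, '#' comments ignored, every data row must
# have the header's field count; errors name the offending line.
.read_tsv_strict <- function(path, n_fields = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop("no content in ", path)
  # sentinel keeps trailing empty fields, which strsplit would drop
  parts <- lapply(strsplit(paste0(lines[keep], "\t\034"), "\t", fixed = TRUE),
                  function(p) p[-length(p)])
  header <- trimws(parts[[1L]])
  nf <- if (is.null(n_fields)) length(header) else n_fields
  for (i in seq_along(parts)[-1L]) {
    if (length(parts[[i]]) != nf)
      stop("malformed row at line ", keep[i], " of ", basename(path),
           ": expected ", nf, " fields, got ", length(parts[[i]]))
  }
  if (length(parts) == 1L) {
    out <- as.data.frame(matrix(character(0), ncol = nf),
                         stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(do.call(rbind, parts[-1L]), stringsAsFactors = FALSE)
  }
  names(out) <- header
  out
}

#' Read a loop design from tab-delimited files
#'
#' @param design_path TSV with columns `array_id`, `tail_unit`, `head_unit`
#'   (arrays kept in file order).
#' @param units_path TSV with columns `unit_id`, `individual`, `section`,
#'   `tech_rep` (empty fields allowed).
#' @param groups_path optional TSV with columns `group`,
#'   `members` (comma-separated sample labels).
#' @return A `loop_design`.
#' @export
read_loop_design <- function(design_path, units_path, groups_path = NULL) {
  ad <- .read_tsv_strict(design_path)
  if (!all(c("array_id", "tail_unit", "head_unit") %in% names(ad)))
    stop("design file needs columns array_id, tail_unit, head_unit")
  ud <- .read_tsv_strict(units_path)
  groups <- list()
  if (!is.null(groups_path)) {
    gd <- .read_tsv_strict(groups_path)
    if (!all(c("group", "members") %in% names(gd)))
      stop("groups file needs columns group, members")
    groups <- setNames(
      lapply(gd$members, function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1L]])),
      gd$group)
  }
  loop_design(
    units = ud,
    arrays = data.frame(array_id = ad$array_id, tail = ad$tail_unit,
                        head = ad$head_unit, stringsAsFactors = FALSE),
    groups = groups
  )
}

#' Read a sample hierarchy from a tab-delimited file
#'
#' @param path TSV with columns `composite`, `children` (comma-separated).
#' @return A `sample_hierarchy`.
#' @export
read_sample_hierarchy <- function(path) {
  hd <- .read_tsv_strict(path)
  if (!all(c("composite", "children") %in% names(hd)))
    stop("hierarchy file needs columns composite, children")
  sample_hierarchy(setNames(
    lapply(hd$children, function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1L]])),
    hd$composite))
}

#' Write a loop design (and optionally a hierarchy) to tab-delimited files
#'
#' Inverse of [read_loop_design()] / [read_sample_hierarchy()]: writes
#' `design.tsv`, `units.tsv`, `groups.tsv` (when groups are declared) and
#' `hierarchy.tsv` (when a hierarchy is given) into `dir`.
#'
#' @param design a `loop_design`.
#' @param dir output directory (created if needed).
#' @param hierarchy optional `sample_hierarchy`.
#' @return Invisibly, the paths written.
#' @export
write_loop_design <- function(design, dir, hierarchy = NULL) {
  stopifnot(inherits(design, "loop_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    p
  }
  paths <- c(paths, wr(data.frame(array_id = design$arrays$array_id,
                                  tail_unit = design$arrays$tail,
                                  head_unit = design$arrays$head),
                       "design.tsv"))
  paths <- c(paths, wr(design$units, "units.tsv"))
  if (length(design$groups)) {
    gd <- data.frame(group = names(design$groups),
                     members = vapply(design$groups, paste, "", collapse = ","))
    paths <- c(paths, wr(gd, "groups.tsv"))
  }
  if (!is.null(hierarchy)) {
    hm <- hierarchy$composite_map
    hd <- data.frame(composite = names(hm),
                     children = vapply(hm, paste, "", collapse = ","))
    paths <- c(paths, wr(hd, "hierarchy.tsv"))
  }
  invisible(paths)
}

#' Read a design, hierarchy and groups from a single JSON file
#'
#' JSON alternative to the TSV dialect: an object with fields `units`
#' (array of objects), `arrays`, and optionally `groups` and `hierarchy`.
#'
#' @param path JSON file.
#' @return list with elements `design` (a `loop_design`) and `hierarchy`
#'   (a `sample_hierarchy`, possibly empty).
#' @export
read_loop_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- as.data.frame(x$units, stringsAsFactors = FALSE)
  arrays <- as.data.frame(x$arrays, stringsAsFactors = FALSE)
  groups <- if (!is.null(x$groups)) lapply(x$groups, as.character) else list()
  hier <- if (!is.null(x$hierarchy))
    sample_hierarchy(lapply(x$hierarchy, as.character))
  else sample_hierarchy()
  list(design = loop_design(units, arrays, groups), hierarchy = hier)
}

#' Validate a loop design and report its structure
#'
#' Reporting-only check of the properties the per-gene model relies on:
#' connectivity of the (undirected) array graph, per-unit dye balance
#' (in/out degree), and group-membership completeness. Never raises; all
#' findings are returned in the report.
#'
#' @param design a `loop_design`.
#' @return An object of class `design_validation`: `n_components`,
#'   `component` (label per unit), `degree` (per-unit in/out), `dye_balanced`,
#'   and `warnings` (character vector, possibly empty).
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "loop_design"))
  comp <- .components(design)
  ids <- design$units$unit_id
  deg <- data.frame(
    unit_id = ids,
    out_degree = vapply(ids, function(u) sum(design$arrays$tail == u), 0L),
    in_degree = vapply(ids, function(u) sum(design$arrays$head == u), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  warnings <- character(0)
  if (max(comp) > 1L)
    warnings <- c(warnings, paste0("array graph has ", max(comp),
                                   " connected components; global fit unavailable"))
  unused <- ids[deg$in_degree + deg$out_degree == 0L]
  if (length(unused))
    warnings <- c(warnings, paste0("unit(s) on no array: ",
                                   paste(unused, collapse = ", ")))
  if (length(design$groups)) {
    member_units <- unlist(design$groups, use.names = FALSE)
    # composite labels are legitimate; only flag declared units on no array
    orphan <- intersect(member_units, unused)
    if (length(orphan))
      warnings <- c(warnings,
                    paste0("group member(s) not hybridized on any array: ",
                           paste(unique(orphan), collapse = ", ")))
  }
  structure(
    list(n_components = max(comp), component = comp, degree = deg,
         dye_balanced = all(deg$in_degree == deg$out_degree),
         warnings = warnings),
    class = "design_validation"
  )
}

#' @export
print.design_validation <- function(x, ...) {
  cat("Design validation\n")
  cat("  components:  ", x$n_components, "\n")
  cat("  dye balance: ",
      if (x$dye_balanced) "in-degree == out-degree for every unit"
      else "unbalanced", "\n")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  } else cat("  no warnings\n")
  invisible(x)
}

#' The twelve-unit interwoven-loop reference design
#'
#' The design the synthetic generator and the examples use throughout: nine
#' individuals (samples 1-9), three tissue sections of individual 8
#' (8-1, 8-2, 8-3), and two technical replicates of section 8-3
#' (8-3_1, 8-3_2) hybridized from one RNA pool — 12 hybridization units in
#' all. Arrays form a doubly interwoven loop: a stride-1 cycle and a
#' stride-2 cycle over the circularly ordered units (24 arrays), so every
#' unit is measured on four arrays with balanced dye assignment. Groups:
#' G1 = individuals 1..9 (8 as the composite of its sections), G2 = the
#' three sections of individual 8, G3 = the two technical replicates.
#'
#' @return list with elements `design` (a `loop_design`) and `hierarchy`
#'   (a `sample_hierarchy` declaring 8-3 = mean(8-3_1, 8-3_2) and
#'   8 = mean(8-1, 8-2, 8-3)).
#' @examples
#' fx <- fig1_design()
#' validate_design(fx$design)
#' @export
fig1_design <- function() {
  dir <- system.file("extdata", "fig1", package = "loopvar")
  design <- read_loop_design(file.path(dir, "design.tsv"),
                             file.path(dir, "units.tsv"),
                             file.path(dir, "groups.tsv"))
  hierarchy <- read_sample_hierarchy(file.path(dir, "hierarchy.tsv"))
  list(design = design, hierarchy = hierarchy)
}
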