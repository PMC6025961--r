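# Genealogy trees from pad-mode lineage tables, with Newick export.

#' Build a genealogy tree from a pad lineage table
#'
#' Validates the parent links (every parent must exist and appear before
#' its daughters; every division must yield exactly two daughters) and
#' assembles, per founder, a strictly binary tree whose branch lengths
#' are cell-cycle durations (min) and whose nodes carry the mean reporter
#' fluorescence over the cell cycle.
#'
#' @param lineage a lineage table with full genealogy (pad mode).
#' @param reporter which reporter's per-cycle mean to annotate
#'   (`"f_alsS"` or `"f_sucC"`).
#' @return An object of class `genealogy_tree`: list with `nodes`
#'   (tibble: `cell_id`, `parent_id`, `birth_t`, `end_t`, `duration_min`,
#'   `mean_f`, `n_daughters`, `founder`) and `newick` (one string per
#'   founder; labels are `c<id>_f<rounded mean fluorescence>`).
#' @examples
#' run <- simulate_pad(switch_params(),
#'                     scenario_config("pad", duration = 240, seed = 1,
#'                                     n_founders = 1))
#' tr <- build_genealogy(run$lineage)
#' tr$newick[[1]]
#' @export
build_genealogy <- function(lineage, reporter = "f_alsS") {
  stopifnot(reporter %in% names(lineage))
  frame_interval <- if (nrow(lineage) > 1) {
    tt <- sort(unique(lineage$t_min)); min(diff(tt))
  } else 12
  sp <- split(lineage, lineage$cell_id)
  nodes <- do.call(rbind, lapply(sp, function(d) data.frame(
    cell_id = d$cell_id[1], parent_id = d$parent_id[1],
    birth_t = min(d$t_min), end_t = max(d$t_min),
    mean_f = mean(d[[reporter]]), n_frames = nrow(d))))
  ids <- nodes$cell_id
  orphans <- nodes$parent_id[!is.na(nodes$parent_id) &
                             !(nodes$parent_id %in% ids)]
  if (length(orphans))
    stop("orphan parent reference(s): ", paste(unique(orphans), collapse = ", "),
         call. = FALSE)
  bad_time <- !is.na(nodes$parent_id) &
    nodes$birth_t <= nodes$birth_t[match(nodes$parent_id, ids)]
  if (any(bad_time))
    stop("daughter born no later than its mother: cell(s) ",
         paste(nodes$cell_id[bad_time], collapse = ", "), call. = FALSE)
  nd <- table(nodes$parent_id)
  not_two <- names(nd)[nd != 2]
  if (length(not_two))
    stop("division with != 2 daughters: cell(s) ",
         paste(not_two, collapse = ", "), call. = FALSE)
  nodes$n_daughters <- as.integer(nd[as.character(nodes$cell_id)])
  nodes$n_daughters[is.na(nodes$n_daughters)] <- 0L
  # duration: birth to division (= first frame of daughters) for divided
  # cells, else to one frame past the last observation
  daughter_birth <- tapply(nodes$birth_t, nodes$parent_id, min)
  nodes$duration_min <- ifelse(
    nodes$n_daughters == 2,
    daughter_birth[as.character(nodes$cell_id)] - nodes$birth_t,
    nodes$end_t + frame_interval - nodes$birth_t)
  founders <- nodes$cell_id[is.na(nodes$parent_id)]
  root_of <- function(cid) {
    repeat {
      pid <- nodes$parent_id[match(cid, ids)]
      if (is.na(pid)) return(cid)
      cid <- pid
    }
  }
  nodes$founder <- vapply(nodes$cell_id, root_of, numeric(1))
  # a divided founder is itself the (labelled) root of a binary tree; a
  # never-dividing founder uses the single-node form "(label:len);"
  newick <- lapply(founders, function(f) {
    body <- .subtree_newick(nodes, f)
    if (nodes$n_daughters[match(f, ids)] == 2) paste0(body, ";")
    else paste0("(", body, ");")
  })
  names(newick) <- paste0("founder_", founders)
  structure(list(nodes = tibble::as_tibble(nodes), newick = newick,
                 frame_interval = frame_interval, reporter = reporter),
            class = "genealogy_tree")
}

.node_label <- function(nodes, cid) {
  i <- match(cid, nodes$cell_id)
  sprintf("c%d_f%d", as.integer(cid), as.integer(round(nodes$mean_f[i])))
}

.subtree_newick <- function(nodes, cid) {
  i <- match(cid, nodes$cell_id)
  lab <- .node_label(nodes, cid)
  len <- format(nodes$duration_min[i], scientific = FALSE, trim = TRUE)
  if (nodes$n_daughters[i] == 2) {
    kids <- nodes$cell_id[!is.na(nodes$parent_id) & nodes$parent_id == cid]
    kids <- kids[order(kids)]
    sprintf("(%s,%s)%s:%s", .subtree_newick(nodes, kids[1]),
            .subtree_newick(nodes, kids[2]), lab, len)
  } else {
    sprintf("%s:%s", lab, len)
  }
}

#' @export
print.genealogy_tree <- function(x, ...) {
  cat(sprintf("<genealogy_tree> %d cells, %d founder(s), %d divisions\n",
              nrow(x$nodes), sum(is.na(x$nodes$parent_id)),
              sum(x$nodes$n_daughters == 2)))
  invisible(x)
}

#' Write / read genealogy Newick files
#'
#' One Newick line per founder tree. Trees with at least two tips
#' round-trip through `ape` (`read.tree`) preserving topology and branch
#' lengths exactly; a never-dividing founder is written as the
#' single-node form `(label:duration);`.
#'
#' @param tree a `genealogy_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "genealogy_tree"))
  writeLines(unlist(tree$newick), path)
  invisible(path)
}

#' Convert a genealogy tree to `ape` phylo objects
#'
#' @param tree a `genealogy_tree`.
#' @return list of `phylo` objects (one per founder with >= 2 tips;
#'   single-cell founders are skipped with a message).
#' @export
genealogy_phylo <- function(tree) {
  stopifnot(inherits(tree, "genealogy_tree"))
  out <- list()
  for (nm in names(tree$newick)) {
    txt <- tree$newick[[nm]]
    if (!grepl(",", txt, fixed = TRUE)) {
      message("founder tree ", nm, " has a single cell; skipped")
      next
    }
    out[[nm]] <- ape::read.tree(text = txt)
  }
  out
}
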