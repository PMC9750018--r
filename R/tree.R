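#' @keywords internal
"_PACKAGE"

# Rooted bifurcating cell phylogeny with a stable, preorder branch numbering
# and precomputed clade structure. Branches are identified by their child
# node, numbered 1..2J-2 in deterministic preorder, so every downstream
# output (posterior vectors, order matrices) is reproducible across runs.

#' Construct a cell phylogeny
#'
#' Builds the internal tree representation used throughout the package from
#' an `ape` `phylo` object or a newick string/file. The tree must be rooted
#' and bifurcating; branches are assigned stable ids in deterministic
#' preorder (root outward, children in input order). A mutation placed on a
#' branch is carried by exactly the tips of the clade below it, so the clade
#' index (descendant branches and tips per branch) is precomputed here.
#'
#' @param x a `phylo` object, a newick string, or a path to a newick file.
#' @param outgroup optional tip label to root on (kept as an ordinary tip).
#' @param resolve_polytomies if `TRUE`, resolve multifurcations
#'   deterministically with zero-length branches; otherwise they are an error.
#' @param default_length branch length to substitute when the source tree has
#'   none; by default missing lengths are an error.
#' @return an object of class `mo_tree` with elements `J` (number of tips),
#'   `tips` (tip labels), `edges` (data frame: `branch`, `parent`, `child`,
#'   `length`, `label`, `is_tip`), `desc_edges`, `desc_tips`,
#'   `parent_branch`, and node-level indices.
#' @examples
#' tr <- mo_tree("((A:1,B:1):1,C:2);")
#' tr$edges
#' @export
mo_tree <- function(x, outgroup = NULL, resolve_polytomies = FALSE,
                    default_length = NULL) {
  phy <- if (inherits(x, "phylo")) x else read_newick_phylo(x)
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label)
      stop("outgroup '", outgroup, "' is not a tip label", call. = FALSE)
    if (!ape::is.rooted(phy) || !is_outgroup_of_root(phy, outgroup))
      phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!ape::is.rooted(phy))
    stop("tree must be rooted (supply an outgroup to root it)", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!ape::is.binary(phy)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them deterministically with zero-length branches",
           call. = FALSE)
    phy <- ape::multi2di(phy, random = FALSE)
    if (!is.null(phy$edge.length))
      phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (is.null(phy$edge.length)) {
    if (is.null(default_length))
      stop("tree has no branch lengths (set default_length to impute)",
           call. = FALSE)
    phy$edge.length <- rep(default_length, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    if (is.null(default_length))
      stop("tree has missing branch lengths (set default_length to impute)",
           call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- default_length
  }
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  build_mo_tree(phy$edge[, 1], phy$edge[, 2], phy$edge.length,
                root = length(phy$tip.label) + 1L,
                tip_labels_of = function(node) {
                  ifelse(node <= length(phy$tip.label),
                         phy$tip.label[node], NA_character_)
                },
                outgroup = outgroup)
}

read_newick_phylo <- function(x) {
  phy <- if (length(x) == 1L && grepl("\\(", x)) {
    tryCatch(ape::read.tree(text = x), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(file = x), error = function(e) NULL)
  }
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("failed to parse newick input", call. = FALSE)
  phy
}

is_outgroup_of_root <- function(phy, outgroup) {
  root <- length(phy$tip.label) + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  match(outgroup, phy$tip.label) %in% kids
}

# Core builder: arbitrary edge table -> canonical mo_tree. `payload` rows are
# carried along and returned reordered to branch-id order (used by the
# subtree projection to keep its branch-path map aligned).
build_mo_tree <- function(parent, child, length, root, tip_labels_of,
                          outgroup = NULL, payload = NULL) {
  stopifnot(length(parent) == length(child),
            length(length) == length(child))
  n_edge <- length(parent)
  kids <- split(seq_len(n_edge), factor(parent, levels = unique(c(root, parent))))
  child_of_edge <- child
  # preorder traversal assigning branch ids
  order_out <- integer(n_edge)
  stack <- as.list(rev(kids[[as.character(root)]]))
  k <- 0L
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    k <- k + 1L
    order_out[k] <- e
    ch <- as.character(child_of_edge[e])
    if (!is.null(kids[[ch]])) for (e2 in rev(kids[[ch]])) stack[[length(stack) + 1L]] <- e2
  }
  if (k != n_edge)
    stop("tree is not connected: unreachable branches from the root",
         call. = FALSE)
  parent <- parent[order_out]; child <- child[order_out]
  length <- length[order_out]
  if (!is.null(payload)) payload <- payload[order_out]

  labels <- vapply(child, tip_labels_of, character(1))
  is_tip <- !is.na(labels)
  # bifurcation check: every node that appears as a parent has exactly 2 kids
  tab <- table(parent)
  if (any(tab != 2L))
    stop("tree is not bifurcating", call. = FALSE)
  J <- sum(is_tip)
  tips <- labels[is_tip]  # preorder tip order
  n_branch <- n_edge
  if (n_branch != 2L * J - 2L)
    stop("branch count ", n_branch, " != 2J-2 for J = ", J, call. = FALSE)

  # renumber nodes canonically: tips 1..J (preorder), internals J+1.. preorder
  old_nodes <- c(root, child)
  new_id <- integer(0)
  new_map <- new.env(hash = TRUE)
  assign(as.character(root), J + 1L, envir = new_map)
  next_int <- J + 2L; next_tip <- 1L
  for (i in seq_len(n_branch)) {
    key <- as.character(child[i])
    if (is_tip[i]) {
      assign(key, next_tip, envir = new_map); next_tip <- next_tip + 1L
    } else {
      assign(key, next_int, envir = new_map); next_int <- next_int + 1L
    }
  }
  re <- function(v) vapply(as.character(v), get, integer(1), envir = new_map)
  parent <- re(parent); child <- re(child)
  root_id <- J + 1L
  labels[!is_tip] <- paste0("n", child[!is_tip])
  tips <- labels[is_tip][order(child[is_tip])]

  edges <- data.frame(branch = seq_len(n_branch), parent = parent,
                      child = child, length = length, label = labels,
                      is_tip = is_tip, stringsAsFactors = FALSE,
                      row.names = NULL)

  branch_above <- integer(max(child, root_id)); branch_above[] <- NA_integer_
  branch_above[child] <- seq_len(n_branch)
  children <- vector("list", max(child, root_id))
  for (b in seq_len(n_branch)) {
    p <- parent[b]
    children[[p]] <- c(children[[p]], b)
  }
  parent_branch <- branch_above[parent]

  # postorder accumulation of clade structure (branches are preorder, so
  # reverse order visits children before parents)
  desc_edges <- vector("list", n_branch)
  desc_tips <- vector("list", n_branch)
  for (b in rev(seq_len(n_branch))) {
    w <- child[b]
    if (is_tip[b]) {
      desc_edges[[b]] <- integer(0)
      desc_tips[[b]] <- w
    } else {
      kb <- children[[w]]
      desc_edges[[b]] <- sort(c(kb, unlist(desc_edges[kb], use.names = FALSE)))
      desc_tips[[b]] <- sort(unlist(desc_tips[kb], use.names = FALSE))
    }
  }

  tr <- structure(list(J = J, tips = tips, root = root_id, edges = edges,
                       children = children, branch_above = branch_above,
                       parent_branch = parent_branch,
                       desc_edges = desc_edges, desc_tips = desc_tips,
                       outgroup = outgroup),
                  class = "mo_tree")
  if (!is.null(payload)) attr(tr, "payload") <- payload
  tr
}

#' @export
print.mo_tree <- function(x, ...) {
  cat("mo_tree:", x$J, "tips,", nrow(x$edges), "branches\n")
  cat("tips:", paste(utils::head(x$tips, 8), collapse = ", "),
      if (x$J > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of branches in a tree
#' @param tree an `mo_tree`.
#' @return integer, equal to 2J - 2 for J tips.
#' @export
n_branches <- function(tree) nrow(tree$edges)

#' Clade structure queries
#'
#' A branch `x = (v, w)` is the ancestor branch of the clade below its child
#' node `w`. `descendant_branches` returns the branch ids inside that clade
#' (excluding `x` itself), `clade_tips` the tip labels it contains, and
#' `is_ancestor_branch(a, b)` tests the strict "earlier than" relation: `a`
#' is earlier than `b` iff `b` lies inside `a`'s clade.
#'
#' @param tree an `mo_tree`.
#' @param branch,a,b branch ids (1-based, preorder).
#' @return `descendant_branches`: integer vector; `clade_tips`: character
#'   vector; `is_ancestor_branch`: logical scalar.
#' @export
descendant_branches <- function(tree, branch) tree$desc_edges[[branch]]

#' @rdname descendant_branches
#' @export
clade_tips <- function(tree, branch) {
  w <- tree$edges$child[branch]
  tipset <- if (tree$edges$is_tip[branch]) w else
    Filter(function(n) n <= tree$J, tree$desc_tips[[branch]])
  tree$tips[sort(unlist(tipset))]
}

#' @rdname descendant_branches
#' @export
is_ancestor_branch <- function(tree, a, b) b %in% tree$desc_edges[[a]]

#' Strict ancestor relation over all branch pairs
#'
#' @param tree an `mo_tree`.
#' @return logical matrix `A` with `A[a, b]` `TRUE` iff branch `a` is a
#'   strict ancestor of branch `b`.
#' @export
ancestor_matrix <- function(tree) {
  n <- n_branches(tree)
  A <- matrix(FALSE, n, n)
  for (a in seq_len(n)) A[a, tree$desc_edges[[a]]] <- TRUE
  A
}

# tip indices (1..J) below a branch
clade_tip_idx <- function(tree, branch) {
  v <- tree$desc_tips[[branch]]
  v[v <= tree$J]
}

#' Are two branches adjacent (parent branch / child branch sharing a node)?
#' @param tree an `mo_tree`.
#' @param a,b branch ids; direction matters: tests whether `b`'s parent
#'   branch is `a`.
#' @return logical scalar.
#' @export
is_adjacent_child <- function(tree, a, b) {
  pb <- tree$parent_branch[b]
  !is.na(pb) && pb == a
}

#' Write a tree as newick
#' @param tree an `mo_tree`.
#' @param file optional path; if `NULL` the newick string is returned.
#' @return the newick string, invisibly if written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  rec <- function(node) {
    kb <- tree$children[[node]]
    if (is.null(kb)) return(tree$tips[node])
    inner <- vapply(kb, function(b) {
      paste0(rec(tree$edges$child[b]), ":", format(tree$edges$length[b], digits = 15))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  s <- paste0(rec(tree$root), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Branch table export
#' @param tree an `mo_tree`.
#' @param file optional TSV path.
#' @return data frame with one row per branch: id, parent/child node, length,
#'   and the comma-separated tips of the clade the branch subtends.
#' @export
branch_table <- function(tree, file = NULL) {
  tab <- tree$edges
  tab$clade_tips <- vapply(tab$branch, function(b)
    paste(tree$tips[clade_tip_idx(tree, b)], collapse = ","), character(1))
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Project a tree onto the cells observed at a site
#'
#' Cells with missing data at a site are excluded; the tree is pruned to the
#' remaining tips and internal nodes left with a single child are suppressed,
#' summing the lengths of the merged path into the retained branch. The
#' mapping from each projected branch back to the ordered path of original
#' branches it merged is retained so posterior mass can later be distributed
#' over original branches.
#'
#' @param tree an `mo_tree`.
#' @param missing_tips character vector of tip labels to drop.
#' @return a list with `tree` (the projected `mo_tree`), `branch_map` (list,
#'   per projected branch, of the original branch ids on its merged path,
#'   root-to-tip order), and `kept_tips`. If no tips are dropped the
#'   projection is the identity.
#' @export
project_subtree <- function(tree, missing_tips = character(0)) {
  missing_tips <- as.character(missing_tips)
  if (!all(missing_tips %in% tree$tips))
    stop("unknown tip labels: ",
         paste(setdiff(missing_tips, tree$tips), collapse = ", "), call. = FALSE)
  kept <- setdiff(tree$tips, missing_tips)
  if (length(kept) < 2L)
    stop("fewer than 2 observed cells remain; posterior undefined for site",
         call. = FALSE)
  if (!length(missing_tips)) {
    return(list(tree = tree,
                branch_map = as.list(seq_len(n_branches(tree))),
                kept_tips = tree$tips))
  }
  keep_tip <- tree$tips %in% kept

  # prune + suppress, accumulating merged branch paths
  prune <- function(node) {
    kb <- tree$children[[node]]
    if (is.null(kb)) {  # tip node
      if (!keep_tip[node]) return(NULL)
      return(list(node = node, tip = tree$tips[node], path = integer(0), len = 0))
    }
    sub <- list()
    for (b in kb) {
      r <- prune(tree$edges$child[b])
      if (!is.null(r)) {
        r$path <- c(b, r$path)
        r$len <- r$len + tree$edges$length[b]
        sub[[length(sub) + 1L]] <- r
      }
    }
    if (!length(sub)) return(NULL)
    if (length(sub) == 1L) return(sub[[1L]])
    list(node = node, kids = sub, path = integer(0), len = 0)
  }
  root_sub <- prune(tree$root)
  # root_sub is the first node with >= 2 kept children; branches above it are
  # outside the projected tree (a mutation there would not be identifiable
  # from the observed cells), matching the 2*J_i - 2 branch count.
  stopifnot(!is.null(root_sub$kids))

  parent <- integer(0); child <- integer(0); lens <- numeric(0)
  paths <- list(); tiplab <- character(0); nid <- 0L
  new_node <- function() { nid <<- nid + 1L; nid }
  emit <- function(sub, parent_id) {
    id <- new_node()
    if (parent_id > 0L) {
      parent <<- c(parent, parent_id); child <<- c(child, id)
      lens <<- c(lens, sub$len); paths[[length(paths) + 1L]] <<- sub$path
    }
    if (is.null(sub$kids)) {
      tiplab[id] <<- sub$tip
    } else {
      tiplab[id] <<- NA_character_
      for (s in sub$kids) emit(s, id)
    }
    id
  }
  root_id <- emit(root_sub, 0L)
  ptree <- build_mo_tree(parent, child, lens, root = root_id,
                         tip_labels_of = function(n) tiplab[n],
                         payload = paths)
  bm <- attr(ptree, "payload"); attr(ptree, "payload") <- NULL
  list(tree = ptree, branch_map = bm, kept_tips = ptree$tips)
}
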