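# Workflow glue: file-level entry points mirroring the `mutorder` CLI
# (inst/cli/mutorder.R): infer, simulate, evaluate. Every output file
# carries a header comment with package version, seed and a config hash so
# runs are traceable.

run_header <- function(seed, config) {
  hash <- sum(utils::head(utf8ToInt(paste(deparse(config), collapse = "")), 1e4) *
                seq_len(min(1e4, nchar(paste(deparse(config), collapse = ""))))) %% 1e8
  sprintf("# mutorder %s seed=%s config=%08d",
          as.character(utils::packageVersion("mutorder")),
          if (is.null(seed)) "NA" else seed, hash)
}

write_tsv_with_header <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run placement inference on a tree and mutation matrix
#'
#' Reads a newick tree and an observed mutation matrix, computes per-site
#' placement posteriors (at fixed parameter values, or integrating over
#' priors by Monte Carlo when `priors` is given), and writes the posterior
#' table, credible sets, pairwise order probabilities, the branch table and
#' a MAP-annotated newick to `out_dir`.
#'
#' @param tree_file newick path (or an [mo_tree]).
#' @param matrix_file mutation matrix path (or an integer matrix).
#' @param mode `"binary"` or `"ternary"`.
#' @param alpha,beta fixed error probabilities (fixed-parameter mode).
#' @param lambda,lambda1,lambda2 fixed transition rates.
#' @param priors optional [prior_spec()]; mutually exclusive with the fixed
#'   parameters.
#' @param theta credible-set complement level.
#' @param seed RNG seed (used by Monte Carlo integration; recorded always).
#' @param out_dir output directory, created if needed.
#' @param outgroup optional tip label used to root the tree.
#' @return invisibly, a list with `posteriors`, `failures`, `map`,
#'   `credible_sets` and the output paths.
#' @export
run_infer <- function(tree_file, matrix_file, mode = c("binary", "ternary"),
                      alpha = NULL, beta = NULL, lambda = NULL,
                      lambda1 = NULL, lambda2 = NULL, priors = NULL,
                      theta = 0.05, seed = 1L, out_dir, outgroup = NULL) {
  mode <- match.arg(mode)
  tree <- if (inherits(tree_file, "mo_tree")) tree_file
          else mo_tree(tree_file, outgroup = outgroup)
  S <- if (is.matrix(matrix_file)) matrix_file
       else read_mutation_matrix(matrix_file, mode)
  if (nrow(S) == 0) stop("mutation matrix is empty", call. = FALSE)
  if (!is.null(priors) && !is.null(alpha))
    stop("give either fixed parameters or priors, not both", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(mode = mode, alpha = alpha, beta = beta, lambda = lambda,
                 lambda1 = lambda1, lambda2 = lambda2,
                 priors = unclass(priors), theta = theta)
  hdr <- run_header(seed, config)

  if (is.null(priors)) {
    res <- mutation_posteriors(tree, S, mode, alpha = alpha, beta = beta,
                               lambda = lambda, lambda1 = lambda1,
                               lambda2 = lambda2)
  } else {
    sites <- rownames(S) %||% paste0("s", seq_len(nrow(S)))
    posts <- vector("list", nrow(S)); fails <- character(0)
    for (i in seq_len(nrow(S))) {
      row <- S[i, ]; names(row) <- colnames(S)
      posts[i] <- list(tryCatch(
        integrate_posterior(tree, row, mode, priors,
                            seed = seed + i, site = sites[i]),
        error = function(e) {
          fails <<- c(fails, paste0(sites[i], ": ", conditionMessage(e)))
          NULL
        }))
    }
    names(posts) <- sites
    res <- list(posteriors = posts, failures = fails)
  }
  posts <- res$posteriors
  ok <- !vapply(posts, is.null, TRUE)
  for (msg in res$failures) warning("site failed: ", msg, call. = FALSE)

  # posterior table (sites x branches)
  pm <- do.call(rbind, lapply(posts[ok], function(p) p$prob))
  ptab <- data.frame(site = names(posts)[ok], pm, check.names = FALSE)
  write_tsv_with_header(ptab, file.path(out_dir, "posteriors.tsv"), hdr)

  # MAP + credible sets
  maps <- lapply(posts[ok], map_location)
  sets <- lapply(posts[ok], credible_set, theta = theta)
  cs <- lapply(seq_along(sets), function(k) list(
    site = names(posts)[ok][k],
    level = sets[[k]]$level,
    branches = tree$edges$label[sets[[k]]$branches],
    cumulative = sets[[k]]$cumulative,
    map = tree$edges$label[as.integer(maps[[k]])],
    map_tie = isTRUE(attr(maps[[k]], "tie"))))
  jsonlite::write_json(list(header = hdr, credible_sets = cs),
                       file.path(out_dir, "credible_sets.json"),
                       auto_unbox = TRUE, digits = NA)

  # pairwise order table
  okn <- names(posts)[ok]
  rows <- list()
  if (sum(ok) >= 2) {
    for (i in seq_len(sum(ok) - 1)) for (j in (i + 1):sum(ok)) {
      po <- pairwise_order(posts[ok][[i]], posts[ok][[j]], tree)
      rows[[length(rows) + 1L]] <- data.frame(
        site_i = okn[i], site_j = okn[j], p_before = po["before"],
        p_after = po["after"], p_same = po["same"],
        p_incomparable = po["incomparable"])
    }
  }
  otab <- if (length(rows)) do.call(rbind, rows)
          else data.frame(site_i = character(0), site_j = character(0),
                          p_before = numeric(0), p_after = numeric(0),
                          p_same = numeric(0), p_incomparable = numeric(0))
  write_tsv_with_header(otab, file.path(out_dir, "pairwise_order.tsv"), hdr)

  branch_table(tree, file.path(out_dir, "branch_table.tsv"))
  writeLines(c(hdr, annotated_newick(tree, posts[ok], maps)),
             file.path(out_dir, "map_annotated.nwk"))
  invisible(list(posteriors = posts, failures = res$failures, map = maps,
                 credible_sets = sets, out_dir = out_dir))
}

# newick with MAP site names appended to the child label of each branch
annotated_newick <- function(tree, posts, maps) {
  by_branch <- split(names(posts),
                     vapply(maps, as.integer, 0L))
  lab <- tree$edges$label
  for (b in names(by_branch)) {
    bi <- as.integer(b)
    lab[bi] <- paste0(lab[bi], "|", paste(by_branch[[b]], collapse = "+"))
  }
  rec <- function(node) {
    kb <- tree$children[[node]]
    if (is.null(kb)) return(NULL)
    inner <- vapply(kb, function(b) {
      ch <- tree$edges$child[b]
      sub <- rec(ch)
      nm <- lab[b]
      paste0(if (is.null(sub)) nm else paste0(sub, nm),
             ":", format(tree$edges$length[b], digits = 15))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

#' Simulate replicate datasets to disk
#'
#' Writes one directory per replicate containing `tree.nwk`, `G.tsv` (true
#' genotypes), `S.tsv` (observed matrix) and `truth.json` (placements,
#' mechanisms, losses, masks, config).
#'
#' @param out_dir output directory.
#' @param replicates number of replicate datasets.
#' @param seed RNG seed; replicate r uses `seed + r`.
#' @param scenario optional scenario name (see [scenario_config()]); sets
#'   defaults for `J` and `tree_method` (grids collapse to their first
#'   value unless overridden).
#' @inheritParams simulate_dataset
#' @return invisibly, the replicate directories.
#' @export
run_simulate <- function(out_dir, replicates = 1L, seed = 1L,
                         scenario = NULL, J = 10, I = 20, mode = "binary",
                         tree_method = "random_split", lambda = 1e-7,
                         lambda1 = 1e-7, lambda2 = 1e-2, alpha = 0, beta = 0,
                         missing = 0, loss_rate = 0, loss_cap = 1L) {
  if (!is.null(scenario)) {
    cfg <- scenario_config(scenario)
    J <- cfg$J[1]; tree_method <- cfg$tree_method
  }
  dirs <- character(replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    d <- file.path(out_dir, sprintf("rep%03d", r))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_dataset(J = J, I = I, mode = mode,
                            tree_method = tree_method, lambda = lambda,
                            lambda1 = lambda1, lambda2 = lambda2,
                            alpha = alpha, beta = beta, missing = missing,
                            loss_rate = loss_rate, loss_cap = loss_cap)
    write_newick(sim$tree, file.path(d, "tree.nwk"))
    write_mutation_matrix(sim$G, file.path(d, "G.tsv"))
    write_mutation_matrix(sim$S, file.path(d, "S.tsv"))
    jsonlite::write_json(
      list(header = run_header(seed + r, sim$config),
           config = sim$config,
           placements = sim$placements,
           losses = sim$losses,
           masked = attr(sim$S, "masked")),
      file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    dirs[r] <- d
  }
  invisible(dirs)
}

#' Evaluate inference output against simulation truth
#'
#' Matches replicate directories between a truth directory (as written by
#' [run_simulate()]) and an inference directory (one [run_infer()] output
#' per replicate, same `repNNN` names), computes the four accuracy metrics
#' per replicate, and pools them by summed counts.
#'
#' @param truth_dir directory of replicate truth.
#' @param inferred_dir directory of replicate inference outputs.
#' @param theta credible-set complement level used at inference time.
#' @param out_file optional TSV path for the metric table.
#' @return data frame of per-replicate and pooled metrics.
#' @export
run_evaluate <- function(truth_dir, inferred_dir, theta = 0.05,
                         out_file = NULL) {
  reps <- sort(list.dirs(truth_dir, recursive = FALSE, full.names = FALSE))
  reps <- reps[grepl("^rep", reps)]
  if (!length(reps)) stop("no replicate directories in ", truth_dir, call. = FALSE)
  missing_reps <- reps[!dir.exists(file.path(inferred_dir, reps))]
  if (length(missing_reps))
    stop("replicates missing from inferred_dir: ",
         paste(missing_reps, collapse = ", "), call. = FALSE)
  per <- list(); pooled <- list()
  for (r in reps) {
    tr <- mo_tree(file.path(truth_dir, r, "tree.nwk"))
    truth <- jsonlite::read_json(file.path(truth_dir, r, "truth.json"),
                                 simplifyVector = TRUE)
    ptab <- utils::read.table(file.path(inferred_dir, r, "posteriors.tsv"),
                              header = TRUE, sep = "\t", comment.char = "#",
                              check.names = FALSE)
    sites <- ptab$site
    pm <- as.matrix(ptab[, -1, drop = FALSE])
    idx <- match(sites, truth$placements$site)
    if (anyNA(idx))
      stop("replicate ", r, ": inferred sites not present in truth", call. = FALSE)
    tb <- truth$placements$branch[idx]
    posts <- lapply(seq_len(nrow(pm)), function(i)
      structure(list(prob = pm[i, ], mode = "binary"), class = "mo_posterior"))
    ev <- evaluate_placements(tr, tb, posts, theta = theta)
    per[[r]] <- ev
  }
  metric_names <- c("location", "order", "adjacent_order", "credible_set")
  rows <- lapply(names(per), function(r) {
    data.frame(replicate = r,
               metric = metric_names,
               numerator = vapply(per[[r]][metric_names], function(x) x$numerator, 0),
               denominator = vapply(per[[r]][metric_names], function(x) x$denominator, 0),
               value = vapply(per[[r]][metric_names], function(x) x$value, 0))
  })
  pooled_rows <- lapply(metric_names, function(mn) {
    pr <- pool_ratios(lapply(per, `[[`, mn))
    data.frame(replicate = "pooled", metric = mn, numerator = pr$numerator,
               denominator = pr$denominator, value = pr$value)
  })
  tab <- do.call(rbind, c(rows, pooled_rows))
  if (!is.null(out_file))
    write_tsv_with_header(tab, out_file, run_header(NA, list(theta = theta)))
  tab
}
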