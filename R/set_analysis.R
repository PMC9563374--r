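# Protein-overlap similarity between response clusters, the agglomerative
# binary similarity tree, and the Venn set algebra over cluster effector sets.

#' Union of effector proteins over a cluster's diseases
#'
#' @param diseases Disease tibble with non-empty effector sets.
#' @param cluster Cluster label (`"DB"`, `"PB"`, `"MPB"` or `"UPB"`).
#' @return Sorted character vector of unique effector identifiers, with the
#'   cluster label attached as the `"label"` attribute.
#' @export
cluster_union <- function(diseases, cluster) {
  sel <- diseases$cluster == cluster
  if (!any(sel)) abort_validation(sprintf("no diseases in cluster '%s'", cluster))
  prot <- sort(unique(unlist(diseases$effectors[sel])))
  if (length(prot) == 0) {
    abort_validation(sprintf("cluster '%s' has an empty effector union", cluster))
  }
  attr(prot, "label") <- cluster
  prot
}

#' All four cluster unions at once
#'
#' @param diseases Disease tibble with non-empty effector sets.
#' @return Named list of sorted character vectors, one per cluster present.
#' @export
cluster_unions <- function(diseases) {
  clusters <- levels(droplevels(diseases$cluster))
  rlang::set_names(purrr::map(clusters, ~ cluster_union(diseases, .x)), clusters)
}

#' Overlap similarity between two protein sets
#'
#' The similarity between sets \eqn{C_1} and \eqn{C_2} is the arithmetic mean
#' of the two proportions of overlap, expressed as a percentage:
#' \deqn{100 \times \frac{O/|C_1| + O/|C_2|}{2}, \quad O = |C_1 \cap C_2|.}
#' It is symmetric, equals 100 iff the sets are identical, and 0 iff they are
#' disjoint.
#'
#' @param set_a,set_b Non-empty character vectors of protein identifiers.
#' @param label_a,label_b Optional labels (default: `"label"` attribute or
#'   `"A"`/`"B"`).
#' @return One-row tibble with `label_a`, `label_b`, `size_a`, `size_b`,
#'   `overlap_count`, `similarity_pct`.
#' @examples
#' overlap_similarity(c("A", "B", "C", "D"),
#'                    c("A", "B", "E", "F", "G", "H", "I", "J"))  # 37.5
#' @export
overlap_similarity <- function(set_a, set_b,
                               label_a = attr(set_a, "label") %||% "A",
                               label_b = attr(set_b, "label") %||% "B") {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (length(a) == 0 || length(b) == 0) abort_validation("empty protein set")
  o <- length(intersect(a, b))
  tibble::tibble(
    label_a = label_a, label_b = label_b,
    size_a = length(a), size_b = length(b),
    overlap_count = o,
    similarity_pct = 100 * (o / length(a) + o / length(b)) / 2
  )
}

#' Pairwise overlap similarity between cluster protein sets
#'
#' @param sets Named list of protein-identifier vectors.
#' @return Tibble of all unordered pairs with their overlap similarity.
#' @export
pairwise_similarity <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  dplyr::bind_rows(purrr::map(pairs, function(p) {
    overlap_similarity(sets[[p[1]]], sets[[p[2]]], p[1], p[2])
  }))
}

#' Agglomerative binary similarity tree over protein sets
#'
#' Repeatedly merges the pair of (groups of) sets with maximal overlap
#' similarity. By default a merged node's protein set is the union of its
#' children and similarities to it are recomputed on that union
#' (`linkage = "union"`); `linkage = "average"` instead averages the leaf-pair
#' similarities. Equal similarities are broken lexicographically on the pair
#' label, making the tree invariant to input order.
#'
#' @param sets Named list of at least two non-empty protein-identifier vectors.
#' @param linkage `"union"` (default) or `"average"`.
#' @return An object of class `ivig_similarity_tree`: list with `merges`
#'   (tibble of `step`, `label_a`, `label_b`, `similarity_pct`,
#'   `merged_label`), `leaves`, `linkage` and `newick` (annotated Newick
#'   string; internal node labels carry the merge similarity).
#' @export
build_similarity_tree <- function(sets, linkage = c("union", "average")) {
  linkage <- match.arg(linkage)
  if (!is.list(sets) || length(sets) < 2) {
    abort_validation("need at least two protein sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_validation("sets must be named")
  }
  leaves <- sort(names(sets))
  active <- sets[leaves]
  members <- rlang::set_names(purrr::map(leaves, ~ .x), leaves)  # leaf labels per group
  newick <- rlang::set_names(as.list(leaves), leaves)
  merges <- list()
  step <- 0
  leaf_sim <- NULL
  if (linkage == "average") {
    leaf_sim <- pairwise_similarity(sets)
  }
  group_sim <- function(la, lb) {
    if (linkage == "union") {
      overlap_similarity(active[[la]], active[[lb]], la, lb)$similarity_pct
    } else {
      pairs <- tidyr::expand_grid(a = members[[la]], b = members[[lb]])
      mean(purrr::map2_dbl(pairs$a, pairs$b, function(x, y) {
        hit <- leaf_sim[(leaf_sim$label_a == x & leaf_sim$label_b == y) |
                        (leaf_sim$label_a == y & leaf_sim$label_b == x), ]
        hit$similarity_pct[1]
      }))
    }
  }
  while (length(active) > 1) {
    labs <- sort(names(active))
    cand <- utils::combn(labs, 2, simplify = FALSE)
    sims <- purrr::map_dbl(cand, ~ group_sim(.x[1], .x[2]))
    # ties broken lexicographically: candidates are generated in sorted order,
    # which.max takes the first maximum
    best <- which.max(sims)
    pair <- cand[[best]]
    step <- step + 1
    merged_label <- paste(sort(c(pair[1], pair[2])), collapse = "+")
    merges[[step]] <- tibble::tibble(
      step = step, label_a = pair[1], label_b = pair[2],
      similarity_pct = sims[best], merged_label = merged_label
    )
    merged_set <- sort(union(active[[pair[1]]], active[[pair[2]]]))
    merged_newick <- sprintf("(%s,%s)%.6g", newick[[pair[1]]], newick[[pair[2]]],
                             sims[best])
    active[[pair[1]]] <- NULL
    active[[pair[2]]] <- NULL
    active[[merged_label]] <- merged_set
    members[[merged_label]] <- sort(c(members[[pair[1]]], members[[pair[2]]]))
    newick[[merged_label]] <- merged_newick
    members[[pair[1]]] <- NULL
    members[[pair[2]]] <- NULL
    newick[[pair[1]]] <- NULL
    newick[[pair[2]]] <- NULL
  }
  structure(list(
    merges = dplyr::bind_rows(merges),
    leaves = leaves,
    linkage = linkage,
    newick = paste0(newick[[1]], ";")
  ), class = "ivig_similarity_tree")
}

#' @export
print.ivig_similarity_tree <- function(x, ...) {
  cat(sprintf("<ivig_similarity_tree> %d leaves, %s linkage\n",
              length(x$leaves), x$linkage))
  print(x$merges)
  invisible(x)
}

#' Convert a similarity tree to an ape phylogeny
#'
#' Internal node labels of the returned tree carry the merge-time overlap
#' similarity (percent).
#'
#' @param tree An `ivig_similarity_tree`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
as_phylo_tree <- function(tree) {
  stopifnot(inherits(tree, "ivig_similarity_tree"))
  ape::read.tree(text = tree$newick)
}

#' Venn partition of the four cluster protein sets
#'
#' Computes the set-difference compartments used downstream for enrichment:
#' `only_db` (proteins exclusive to the DB cluster), `db_without_upb`
#' (DB proteins absent from UPB), `only_upb`, and `shared_all` (present in all
#' four clusters).
#'
#' @param db,pb,mpb,upb Non-empty character vectors of protein identifiers.
#' @return An object of class `venn_partition`: list of the four sorted
#'   protein vectors plus `sizes`.
#' @export
venn_partition <- function(db, pb, mpb, upb) {
  sets <- list(db = db, pb = pb, mpb = mpb, upb = upb)
  if (any(lengths(sets) == 0)) abort_validation("all four cluster sets must be non-empty")
  sets <- purrr::map(sets, ~ unique(as.character(.x)))
  out <- list(
    only_db = sort(setdiff(sets$db, Reduce(union, sets[c("pb", "mpb", "upb")]))),
    db_without_upb = sort(setdiff(sets$db, sets$upb)),
    only_upb = sort(setdiff(sets$upb, Reduce(union, sets[c("db", "pb", "mpb")]))),
    shared_all = sort(Reduce(intersect, sets))
  )
  out$sizes <- purrr::map_int(out[1:4], length)
  structure(out, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  print(x$sizes)
  invisible(x)
}
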