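# Shared fixtures, built in code.

# 5-cell, 8-branch tree of the worked binary example: a mutation on the
# trunk branch is carried by cells C1..C4; the outgroup-side cell C5 is not.
worked_newick <- function() {
  "((((C1:0.3,C2:0.4):0.2,C3:0.5):0.15,C4:0.6):0.25,C5:0.7);"
}

worked_tree <- function() mo_tree(worked_newick())

# branch id by the label of its child node
branch_by_label <- function(tree, label) {
  match(label, tree$edges$label)
}

# trunk branch of worked_tree: the non-tip child of the root
trunk_branch <- function(tree) {
  kids <- tree$children[[tree$root]]
  kids[!tree$edges$is_tip[kids]][1]
}

# worked order-accuracy fixture: tree plus true and inferred placements for
# mutations m1..m5, constructed so the true ordered pairs are
# (m1,m2),(m1,m3),(m1,m4),(m1,m5),(m3,m4),(m3,m5) and the true adjacent
# pairs (m1,m2),(m3,m4),(m3,m5); the inferred mapping gets (m3,m5) wrong by
# collapsing m5 onto m3's branch.
order_fixture <- function() {
  tr <- mo_tree("((C2:1,(C3:1,(C4:1,C5:1):1):1):1,N:1);")
  b <- function(lab) branch_by_label(tr, lab)
  trunk <- trunk_branch(tr)                     # branch above the tumor clade
  w <- tr$edges$branch[!tr$edges$is_tip & tr$edges$branch != trunk]
  # w has two internal branches below the trunk: v (above C3 split) then
  # the branch carrying the (C4,C5) cherry
  v <- w[1]; cherry <- w[2]
  truth <- c(m1 = trunk, m2 = b("C2"), m3 = cherry, m4 = b("C4"),
             m5 = b("C5"))
  inferred <- truth
  inferred["m5"] <- cherry
  list(tree = tr, truth = truth, inferred = inferred)
}

# deterministic random bifurcating tree with exponential lengths
random_tree <- function(J, mean_len = 0.3) {
  simulate_tree(J, "random_split", mean_branch_length = mean_len)
}
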