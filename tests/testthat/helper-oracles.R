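# independent oracles: these never touch the state-space assembly

# DC (purely resistive) nodal analysis of a network: inductors become
# shorts, capacitors open, sources sit at their time-mean pressure.
# Returns the mean flow through every branch, named by branch label.
dc_nodal_flow <- function(network) {
  nd <- network$nodes
  br <- network$branches
  u <- vapply(network$sources, function(s) s$fourier$a0, numeric(1))
  known <- c(`0` = 0)  # ground
  for (i in seq_len(nrow(nd))) {
    if (!is.na(nd$pin[i])) known[as.character(nd$node[i])] <- u[[nd$pin[i]]]
  }
  free <- setdiff(nd$node, as.integer(names(known)))
  G <- matrix(0, length(free), length(free),
              dimnames = list(free, free))
  b <- stats::setNames(numeric(length(free)), free)
  for (k in seq_len(nrow(br))) {
    g <- 1 / br$R[k]
    ends <- c(br$from[k], br$to[k])
    for (e in 1:2) {
      n1 <- as.character(ends[e])
      n2 <- as.character(ends[3 - e])
      if (!n1 %in% rownames(G)) next
      G[n1, n1] <- G[n1, n1] + g
      if (n2 %in% rownames(G)) {
        G[n1, n2] <- G[n1, n2] - g
      } else {
        b[n1] <- b[n1] + g * known[[n2]]
      }
    }
  }
  p <- stats::setNames(numeric(0), character(0))
  if (length(free)) p <- stats::setNames(drop(solve(G, b)), free)
  pall <- c(known, p)
  flows <- (pall[as.character(br$from)] - pall[as.character(br$to)]) / br$R
  stats::setNames(unname(flows), br$label)
}

# closed-form input impedance of the 3-element Windkessel at angular
# frequency w (0 gives the DC resistance R_p + R_d)
wk3_impedance <- function(R_p, R_d, C, w) {
  R_p + R_d / (1 + 1i * w * R_d * C)
}
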