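# shared fixtures, built in code

three_tip <- function() read_newick("((A:1,B:1):1,C:2);")

balanced_four <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr
}

# small taxonomy covering a genus pair and a second genus
toy_taxonomy <- function() {
  data.frame(species = c("A_gen1", "B_gen1", "C_gen2", "D_gen1", "E_gen3"),
             genus = c("gen1", "gen1", "gen2", "gen1", "gen3"),
             family = c("fam1", "fam1", "fam1", "fam1", "fam2"),
             order = "ord1",
             stringsAsFactors = FALSE)
}

# dense joint-Gaussian log-likelihood, independent of the package internals
dense_mvn_loglik <- function(C, Y, R, mu) {
  Sigma <- kronecker(R, C)
  m <- rep(mu, each = nrow(Y))
  v <- as.vector(Y)
  o <- !is.na(v)
  r <- v[o] - m[o]
  So <- Sigma[o, o, drop = FALSE]
  -0.5 * (sum(o) * log(2 * pi) +
            as.numeric(determinant(So, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(So, r)))
}

# dense conditional mean/variance of missing cells given observed
dense_conditional <- function(C, Y, R, mu) {
  Sigma <- kronecker(R, C)
  m <- rep(mu, each = nrow(Y))
  v <- as.vector(Y)
  o <- !is.na(v)
  So <- Sigma[o, o, drop = FALSE]
  Smo <- Sigma[!o, o, drop = FALSE]
  list(mean = m[!o] + drop(Smo %*% solve(So, v[o] - m[o])),
       var = diag(Sigma[!o, !o, drop = FALSE] -
                    Smo %*% solve(So, t(Smo))))
}
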