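# shared fixture builders

# cosine similarity between rows of two matrices
row_cosine <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# a MomentSet built directly from given per-cell moment vectors
make_momentset <- function(m_u, m_s, v_s = NULL, m_us = NULL,
                           gene_ids = "g1") {
  as_col <- function(x) if (is.null(x)) NULL else matrix(x, ncol = 1)
  structure(list(m_u = as_col(m_u), m_s = as_col(m_s),
                 v_u = as_col(m_u^2), v_s = as_col(v_s),
                 m_us = as_col(m_us), n_cells = length(m_u),
                 gene_ids = gene_ids),
            class = "MomentSet")
}

# linear vector field v = A x as a FunctionField with analytic Jacobian
linear_field <- function(A) {
  as_vectorfield(function(X) X %*% t(A), jacobian = function(x) A,
                 d = ncol(A))
}

# noiseless one-shot fixture: l = k * r exactly
one_shot_fixture <- function(k = 0.5, t = 1, n = 40) {
  r <- matrix(seq(10, 100, length.out = n), ncol = 1)
  layered_matrix(list(l = r * k, r = r), label_time = t,
                 experiment_type = "one_shot")
}
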