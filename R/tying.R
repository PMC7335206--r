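# Parameter tying across segment classes and photophysical states.
#
# The blinking models need acceptor fractions for the dark states. Those are
# not free: a molecule with A1 dark emits like a DA2 molecule and one with A2
# dark like a DA1 molecule, so the dark-state three-color fractions are
# expressed through the two-color fractions. The mapping used here (one
# place, below) is, for conformational state S:
#
#   (j, k) = (b, b):  eps1 = eps1_S,              eps2 = eps2_S
#   (j, k) = (b, d):  eps1 = epsDA1_S * (1-l12),  eps2 = epsDA1_S * l12
#   (j, k) = (d, b):  eps1 = 0,                   eps2 = epsDA2_S
#   (j, k) = (d, d):  eps1 = 0,                   eps2 = 0
#
# i.e. with A2 dark the acceptor signal is the DA1 fraction, split between
# the A1 and A2 channels by the A1-into-A2 leak l12 (0 when no correction
# factors are supplied); with A1 dark all acceptor photons appear in the A2
# channel at the DA2 fraction. With both acceptors dark only donor photons
# remain. For binding, the unbound-state ratio relation
# eps2Bd / eps1Bd = eps2U / eps1U removes one further fraction.

#' Expand a free parameter set into the per-state emission fractions
#'
#' Applies the tying relations of a model family, turning the family's
#' independent acceptor fractions into the full emission set the matrix
#' builders need. Families without tying return the input unchanged.
#'
#' @param params Named list of free parameters (see the family docs).
#' @param family One of `"folding_2c"`, `"folding_3c"`, `"folding_global"`,
#'   `"folding_global_blink"`, `"binding_global"`, `"binding_global_blink"`.
#' @param l12 A1-into-A2 leak fraction used to split the A2-dark emission
#'   between the acceptor channels (default 0).
#' @return The parameter list, completed with derived entries (for blinking
#'   families, `eps1_3c`/`eps2_3c` length-8 vectors in builder state order).
#' @export
apply_tying <- function(params, family, l12 = 0) {
  p <- as.list(params)
  switch(family,
    folding_global_blink = {
      tie1 <- function(S) {
        c(bb = p[[paste0("eps1_", S)]],
          bd = p[[paste0("epsDA1_", S)]] * (1 - l12),
          db = 0,
          dd = 0)
      }
      tie2 <- function(S) {
        c(bb = p[[paste0("eps2_", S)]],
          bd = p[[paste0("epsDA1_", S)]] * l12,
          db = p[[paste0("epsDA2_", S)]],
          dd = 0)
      }
      # builder state order: Fbb, Ubb, Fbd, Ubd, Fdb, Udb, Fdd, Udd
      ord <- c("bb", "bd", "db", "dd")
      p$eps1_3c <- as.numeric(rbind(tie1("F")[ord], tie1("U")[ord]))
      p$eps2_3c <- as.numeric(rbind(tie2("F")[ord], tie2("U")[ord]))
      p
    },
    binding_global = {
      if (is.null(p$eps2_U)) {
        if (is.null(p$eps2_Bd)) stop("need eps2_Bd or eps2_U", call. = FALSE)
        if (p$eps1_Bd == 0 || p$eps1_U == 0) {
          stop("eps1_Bd = 0 or eps1_U = 0: unbound-ratio tying undefined",
               call. = FALSE)
        }
        p$eps2_U <- p$eps1_U * p$eps2_Bd / p$eps1_Bd
      } else if (is.null(p$eps2_Bd)) {
        if (p$eps1_U == 0) stop("eps1_U = 0: unbound-ratio tying undefined", call. = FALSE)
        p$eps2_Bd <- p$eps1_Bd * p$eps2_U / p$eps1_U
      }
      p
    },
    binding_global_blink = {
      if (p$eps1_Ubb == 0) stop("eps1_Ubb = 0: unbound-ratio tying undefined", call. = FALSE)
      p$eps2_Bbd <- p$eps1_Bbd * p$eps2_Ubb / p$eps1_Ubb
      # state order: Bbb, Ubb, Bbx, Bbd, Bdb, Udb, Bdx, Bdd
      p$eps1_3c <- c(p$eps1_Bbb, p$eps1_Ubb, p$eps1_Bbd, p$eps1_Bbd, 0, 0, 0, 0)
      p$eps2_3c <- c(p$eps2_Bbb, p$eps2_Ubb, p$eps2_Bbd, p$eps2_Bbd,
                     p$epsDA2_B, p$epsDA2_U, p$epsDA2_U, p$epsDA2_U)
      p
    },
    p
  )
}

# free parameter names per fit family (after tying)
family_param_names <- function(family, n_states = 2) {
  switch(family,
    static_2c = "eps",
    folding_2c = c("k", "p_F", "eps_F", "eps_U"),
    folding_3c = c("k", "p_F", "eps1_F", "eps2_F", "eps1_U", "eps2_U"),
    folding_global = c("k", "p_F", "eps1_F", "eps2_F", "eps1_U", "eps2_U",
                       "epsDA1_F", "epsDA1_U", "epsDA2_F", "epsDA2_U"),
    folding_global_blink = c("k", "p_F", "eps1_F", "eps2_F", "eps1_U", "eps2_U",
                             "epsDA1_F", "epsDA1_U", "epsDA2_F", "epsDA2_U",
                             "kb1", "kd10", "kb2", "kd20"),
    binding_global = c("eps1_Bb", "eps2_Bb", "eps1_Bd", "eps2_Bd", "eps1_U",
                       "epsDA2_B", "epsDA2_U", "k_B", "k_U", "phi", "kb2p", "kd2p"),
    binding_global_blink = c("eps1_Bbb", "eps2_Bbb", "eps1_Ubb", "eps2_Ubb",
                             "eps1_Bbd", "epsDA2_B", "epsDA2_U", "k_B", "k_U",
                             "kb1", "kd10", "kb2", "kd20", "phi", "kb2p", "kd2p"),
    linear_2c = c(paste0("k", seq_len(n_states - 1), seq_len(n_states - 1) + 1),
                  paste0("k", seq_len(n_states - 1) + 1, seq_len(n_states - 1)),
                  paste0("eps", seq_len(n_states))),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Number of independently optimized parameters of a model family
#'
#' The count after all tying relations, as used in the BIC penalty:
#' 14 for global two-state folding with blinking, 16 for global two-state
#' binding with blinking, 12 for binding without blinking.
#'
#' @inheritParams apply_tying
#' @param n_states Number of states for the linear-chain family.
#' @export
count_free_parameters <- function(family, n_states = 2) {
  length(family_param_names(family, n_states))
}

#' Number of independent three-color acceptor fractions of a family
#'
#' For the binding model without blinking the unbound-state ratio relation
#' reduces the six three-color fractions to five.
#'
#' @inheritParams count_free_parameters
#' @export
independent_fractions <- function(family, n_states = 2) {
  nm <- family_param_names(family, n_states)
  sum(grepl("^eps[12]_", nm))
}
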