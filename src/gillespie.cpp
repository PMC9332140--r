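#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie SSA) of one gene in one cell:
// two-state promoter (I -> A at k_on, A -> I at k_off), transcription at
// alpha_on (active) / alpha_off (inactive), optional splicing at beta per
// unspliced molecule, degradation at gamma per (spliced) molecule.
// Molecules transcribed while labeling is on are labeled with probability
// rho. Phases per cell: burn-in (no labels), labeling window, chase.
// Without splicing the transcript goes straight to the "spliced" pool,
// which then represents total RNA with first-order decay gamma.

struct CellState {
  int active;
  int uu, ul, su, sl;
};

static void run_phase(CellState &st, double t_end, bool labeling,
                      double kon, double koff, double alpha_on,
                      double alpha_off, double beta, double gamma,
                      double rho, bool splicing) {
  double t = 0.0;
  while (true) {
    double a_sw = st.active ? koff : kon;
    double a_tx = st.active ? alpha_on : alpha_off;
    double a_sp = splicing ? beta * (st.uu + st.ul) : 0.0;
    double a_dg = gamma * (st.su + st.sl);
    double a0 = a_sw + a_tx + a_sp + a_dg;
    if (a0 <= 0.0) break;
    double dt = R::rexp(1.0 / a0);
    if (t + dt > t_end) break;
    t += dt;
    double r = R::runif(0.0, a0);
    if (r < a_sw) {
      st.active = 1 - st.active;
    } else if (r < a_sw + a_tx) {
      bool lab = labeling && (rho >= 1.0 || R::runif(0.0, 1.0) < rho);
      if (splicing) {
        if (lab) st.ul++; else st.uu++;
      } else {
        if (lab) st.sl++; else st.su++;
      }
    } else if (r < a_sw + a_tx + a_sp) {
      // pick an unspliced molecule uniformly
      double u = R::runif(0.0, (double)(st.uu + st.ul));
      if (u < st.uu) { st.uu--; st.su++; } else { st.ul--; st.sl++; }
    } else {
      double s = R::runif(0.0, (double)(st.su + st.sl));
      if (s < st.su) st.su--; else st.sl--;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix simulate_cells_cpp(int n_cells, double kon, double koff,
                                 double alpha_on, double alpha_off,
                                 double beta, double gamma, double rho,
                                 bool splicing, double t_burn,
                                 NumericVector t_label,
                                 NumericVector t_chase) {
  IntegerMatrix out(n_cells, 5); // active, uu, ul, su, sl
  for (int i = 0; i < n_cells; ++i) {
    CellState st;
    // start the promoter from its stationary distribution
    double p_on = kon / (kon + koff);
    st.active = R::runif(0.0, 1.0) < p_on ? 1 : 0;
    st.uu = st.ul = st.su = st.sl = 0;
    run_phase(st, t_burn, false, kon, koff, alpha_on, alpha_off, beta,
              gamma, rho, splicing);
    if (t_label[i] > 0.0)
      run_phase(st, t_label[i], true, kon, koff, alpha_on, alpha_off,
                beta, gamma, rho, splicing);
    if (t_chase[i] > 0.0)
      run_phase(st, t_chase[i], false, kon, koff, alpha_on, alpha_off,
                beta, gamma, rho, splicing);
    out(i, 0) = st.active;
    out(i, 1) = st.uu;
    out(i, 2) = st.ul;
    out(i, 3) = st.su;
    out(i, 4) = st.sl;
  }
  return out;
}
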