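#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the cell-level rules underlying the
// compartment model, with optional BrdU labelling during [t_hat,
// t_hat + delta]. Counts are population-level (all rates are linear, so
// per-cell identity is never needed); each compartment tracks the total and
// the labelled subpopulation. Uses R's RNG stream (seed with set.seed()).
//
// pars: a1, theta1, p1, kappa, a2, theta2, p2, d2, p3, d3, d4, d5
// Returns a matrix length(out_times) x 10: N1..N5, L1..L5, sampled just
// before the first event at or after each output time.
// [[Rcpp::export]]
NumericMatrix sim_gillespie_cpp(NumericVector pars, NumericVector init_total,
                                NumericVector init_lab, double t_hat,
                                double delta, NumericVector out_times,
                                double max_events) {
  const double a1 = pars[0], th1 = pars[1], p1 = pars[2], kap = pars[3];
  const double a2 = pars[4], th2 = pars[5], p2 = pars[6], d2 = pars[7];
  const double p3 = pars[8], d3 = pars[9], d4 = pars[10], d5 = pars[11];

  double N[5], L[5];
  for (int i = 0; i < 5; ++i) { N[i] = init_total[i]; L[i] = init_lab[i]; }

  const int nout = out_times.size();
  NumericMatrix out(nout, 10);
  int k = 0;
  double t = 0.0, events = 0.0;

  auto record_until = [&](double tnext) {
    while (k < nout && out_times[k] < tnext) {
      for (int i = 0; i < 5; ++i) { out(k, i) = N[i]; out(k, 5 + i) = L[i]; }
      ++k;
    }
  };
  auto bern = [](double p) { return unif_rand() < p ? 1.0 : 0.0; };

  while (k < nout) {
    const double rStem = p1 * N[0];
    const double rProg = p2 * N[1], rProgD = d2 * N[1];
    const double rMat = p3 * N[2], rNbD = d3 * N[2];
    const double rNeuD = d4 * N[3], rAstD = d5 * N[4];
    const double R = rStem + rProg + rProgD + rMat + rNbD + rNeuD + rAstD;
    if (R <= 0.0) {  // absorbed: no further events, flush remaining outputs
      record_until(R_PosInf);
      break;
    }
    const double tnext = t + exp_rand() / R;
    record_until(tnext);
    if (k >= nout) break;
    if (++events > max_events)
      stop("event cap exceeded (%.0f events); population exploding?", max_events);

    const bool inWindow = delta > 0.0 && tnext >= t_hat && tnext <= t_hat + delta;
    double u = unif_rand() * R;

    if (u < rStem) {
      const double mlab = bern(L[0] / N[0]);
      if (unif_rand() < th1) {  // division
        const double dlab = (inWindow || mlab > 0.5) ? 1.0 : 0.0;
        if (unif_rand() < 2.0 * a1 - 1.0) {  // symmetric: two stem daughters
          N[0] += 1.0; L[0] += 2.0 * dlab - mlab;
        } else {  // asymmetric: stem + (progenitor | astrocyte)
          L[0] += dlab - mlab;
          if (unif_rand() < kap) { N[1] += 1.0; L[1] += dlab; }
          else                   { N[4] += 1.0; L[4] += dlab; }
        }
      } else {  // astrocytic transformation, no DNA synthesis
        N[0] -= 1.0; L[0] -= mlab; N[4] += 1.0; L[4] += mlab;
      }
    } else if (u < rStem + rProg) {
      const double mlab = bern(L[1] / N[1]);
      if (unif_rand() < th2) {  // division
        const double dlab = (inWindow || mlab > 0.5) ? 1.0 : 0.0;
        if (unif_rand() < 2.0 * a2 - 1.0) {  // symmetric: two progenitors
          N[1] += 1.0; L[1] += 2.0 * dlab - mlab;
        } else {  // asymmetric: progenitor + neuroblast
          L[1] += dlab - mlab; N[2] += 1.0; L[2] += dlab;
        }
      } else {  // transformation to neuroblast
        N[1] -= 1.0; L[1] -= mlab; N[2] += 1.0; L[2] += mlab;
      }
    } else if (u < rStem + rProg + rProgD) {
      const double mlab = bern(L[1] / N[1]);
      N[1] -= 1.0; L[1] -= mlab;
    } else if (u < rStem + rProg + rProgD + rMat) {
      const double mlab = bern(L[2] / N[2]);
      N[2] -= 1.0; L[2] -= mlab; N[3] += 1.0; L[3] += mlab;
    } else if (u < rStem + rProg + rProgD + rMat + rNbD) {
      const double mlab = bern(L[2] / N[2]);
      N[2] -= 1.0; L[2] -= mlab;
    } else if (u < rStem + rProg + rProgD + rMat + rNbD + rNeuD) {
      const double mlab = bern(L[3] / N[3]);
      N[3] -= 1.0; L[3] -= mlab;
    } else {
      const double mlab = bern(L[4] / N[4]);
      N[4] -= 1.0; L[4] -= mlab;
    }
    t = tnext;
  }
  return out;
}
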