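#include <Rcpp.h>
using namespace Rcpp;

// Lattice-walk Monte Carlo of diffusing emitters in a 3D Gaussian detection
// volume. Each time slice every particle jumps its species step along one of
// the six axis directions (prob 1/6 each) with periodic wrapping at the box
// faces, then the slice photon count is drawn as Poisson of the summed
// per-particle intensity phi0_i * PSF(r_i) (sum of independent Poissons).
// Uses R's RNG: deterministic under set.seed().
//
// pos: 3 x P matrix (um), modified in place copy; step, phi0: per particle;
// bright: initial emission state; p_dark/p_bright: per-slice switching
// probabilities (bright->dark, dark->bright); agg: slices per output bin.
// [[Rcpp::export(name = ".sim_lattice_trace")]]
IntegerVector sim_lattice_trace(int n_out, int agg,
                                NumericMatrix pos,
                                NumericVector step,
                                NumericVector phi0,
                                double r0, double z0,
                                double half_x, double half_z,
                                LogicalVector bright,
                                double p_dark, double p_bright) {
  const int P = pos.ncol();
  if (step.size() != P || phi0.size() != P || bright.size() != P)
    stop("per-particle vectors must match the number of particles");
  const double inv_r02 = 2.0 / (r0 * r0);
  const double inv_z02 = 2.0 / (z0 * z0);
  const double span_x = 2.0 * half_x, span_z = 2.0 * half_z;
  const bool blink = (p_dark > 0.0 || p_bright > 0.0);

  std::vector<double> x(P), y(P), z(P), st(P), ph(P);
  std::vector<int> on(P);
  for (int p = 0; p < P; ++p) {
    x[p] = pos(0, p); y[p] = pos(1, p); z[p] = pos(2, p);
    st[p] = step[p]; ph[p] = phi0[p]; on[p] = bright[p] ? 1 : 0;
  }

  IntegerVector out(n_out);
  RNGScope scope;
  for (int b = 0; b < n_out; ++b) {
    long acc = 0;
    for (int s = 0; s < agg; ++s) {
      double lambda = 0.0;
      for (int p = 0; p < P; ++p) {
        const int dir = (int)(unif_rand() * 6.0);
        const double e = st[p];
        switch (dir) {
          case 0: x[p] += e; if (x[p] >  half_x) x[p] -= span_x; break;
          case 1: x[p] -= e; if (x[p] < -half_x) x[p] += span_x; break;
          case 2: y[p] += e; if (y[p] >  half_x) y[p] -= span_x; break;
          case 3: y[p] -= e; if (y[p] < -half_x) y[p] += span_x; break;
          case 4: z[p] += e; if (z[p] >  half_z) z[p] -= span_z; break;
          default: z[p] -= e; if (z[p] < -half_z) z[p] += span_z; break;
        }
        if (blink) {
          if (on[p]) { if (unif_rand() < p_dark) on[p] = 0; }
          else       { if (unif_rand() < p_bright) on[p] = 1; }
          if (!on[p]) continue;
        }
        if (ph[p] > 0.0)
          lambda += ph[p] * std::exp(-(x[p] * x[p] + y[p] * y[p]) * inv_r02
                                     - z[p] * z[p] * inv_z02);
      }
      if (lambda > 0.0) acc += (long)R::rpois(lambda);
    }
    if (acc > INT_MAX) stop("photon count overflow in one output bin");
    out[b] = (int)acc;
    if ((b & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
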