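#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of n independent linear birth-death processes
// (per-cell birth rate alpha, death rate beta) started from z0 cells, run
// until extinction or first passage at `ceiling` cells. Uses R's RNG so
// results are reproducible under set.seed().
//
// If q_cond >= 0 the process is instead the Doob h-transform conditioned
// on eventual survival (h(i) = 1 - q^i with q = q_cond = beta/alpha):
// from size i the birth rate becomes i*alpha*(1-q^{i+1})/(1-q^i) and the
// death rate i*beta*(1-q^{i-1})/(1-q^i), so extinction is unreachable and
// the first-passage time at the ceiling has exactly the law of T_M given
// non-extinction. q^i is tracked multiplicatively and underflows to the
// unconditioned rates at large sizes, as it should.
//
// Returns an n x 2 matrix: column 0 is the fate (0 = extinct, 1 = reached
// the ceiling), column 1 the absorption / first-passage time in days.
// [[Rcpp::export]]
NumericMatrix bd_first_passage_cpp(int n, double alpha, double beta,
                                   double ceiling, double z0,
                                   double q_cond = -1.0) {
  if (n < 0) stop("n must be non-negative");
  if (alpha <= 0 || beta < 0) stop("need alpha > 0 and beta >= 0");
  if (ceiling < 1 || z0 < 1 || z0 > ceiling)
    stop("need 1 <= z0 <= ceiling");
  if (q_cond >= 1.0) stop("q_cond must be below 1");
  NumericMatrix out(n, 2);
  const double p_birth = alpha / (alpha + beta);
  const double total = alpha + beta;
  const bool cond = q_cond >= 0.0;
  for (int r = 0; r < n; ++r) {
    double z = z0, t = 0.0;
    double qz = cond ? std::pow(q_cond, z0) : 0.0;  // q^z, kept in step
    while (z > 0.0 && z < ceiling) {
      if (cond && qz > 0.0) {
        const double up = alpha * (1.0 - qz * q_cond);
        const double down = beta * (1.0 - qz / q_cond);
        t += R::exp_rand() / (z * (up + down) / (1.0 - qz));
        if (R::unif_rand() < up / (up + down)) {
          z += 1.0; qz *= q_cond;
        } else {
          z -= 1.0; qz /= q_cond;
        }
      } else {
        t += R::exp_rand() / (z * total);
        if (R::unif_rand() < p_birth) z += 1.0; else z -= 1.0;
      }
    }
    out(r, 0) = (z >= ceiling) ? 1.0 : 0.0;
    out(r, 1) = t;
  }
  return out;
}
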