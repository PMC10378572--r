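#include <Rcpp.h>
using namespace Rcpp;

// Leapfrog kernel for u_tt = c^2 u_xx + f on x in [0, L], uniform grid of
// nx+1 nodes, nt time samples. Glottal end (node 0): Dirichlet u = a(t).
// Lip end (node nx): zero-gradient Neumann via a ghost node, with an
// optional flux drive q(t) (ghost value u[nx+1] = u[nx-1] + 2*dx*q), or a
// first-order Sommerfeld (absorbing) condition. The scheme starts from rest
// (u = 0 at the two fictitious initial levels), which keeps the map from
// inputs to the lip trace exactly time-invariant (convolutional) - the
// property the discrete adjoint identity relies on.
//
// a   : Dirichlet data at node 0, length nt (may be all zero)
// q   : Neumann flux drive at node nx, length nt (may be empty = no drive)
// f   : source, (nx+1) x nt matrix (may be 0 x 0 = no source)
// C2  : (c*dt/dx)^2, must be <= 1
// dt2 : dt^2
// dx  : grid spacing (only used to scale q)
// absorbing : use Sommerfeld lip condition instead of Neumann
// [[Rcpp::export(name = ".wave_leapfrog")]]
NumericMatrix wave_leapfrog(NumericVector a, NumericVector q,
                            NumericMatrix f, int nx, double C2,
                            double dt2, double dx, bool absorbing) {
  const int nt = a.size();
  const bool has_f = f.nrow() > 0;
  const bool has_q = q.size() > 0;
  const double C1 = std::sqrt(C2);
  NumericMatrix u(nx + 1, nt);
  std::vector<double> up(nx + 1, 0.0), uk(nx + 1, 0.0), un(nx + 1, 0.0);
  uk[0] = a[0];
  u(0, 0) = a[0];
  for (int k = 0; k < nt - 1; ++k) {
    for (int i = 1; i < nx; ++i) {
      double src = has_f ? dt2 * f(i, k) : 0.0;
      un[i] = 2.0 * uk[i] - up[i]
            + C2 * (uk[i + 1] - 2.0 * uk[i] + uk[i - 1]) + src;
    }
    if (absorbing) {
      // first-order upwind transport out of the domain
      un[nx] = uk[nx] - C1 * (uk[nx] - uk[nx - 1]);
      if (has_f) un[nx] += dt2 * f(nx, k);
    } else {
      double drive = has_q ? dx * q[k] : 0.0;
      double src = has_f ? dt2 * f(nx, k) : 0.0;
      un[nx] = 2.0 * uk[nx] - up[nx]
             + 2.0 * C2 * (uk[nx - 1] - uk[nx] + drive) + src;
    }
    un[0] = a[k + 1];
    std::swap(up, uk);
    std::swap(uk, un);
    for (int i = 0; i <= nx; ++i) u(i, k + 1) = uk[i];
  }
  return u;
}
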