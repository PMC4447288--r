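#include <Rcpp.h>
using namespace Rcpp;

// Evaluate a 3D thin-plate spline (biharmonic kernel U(r) = -r) at a set
// of points: out = U(|X - anchors|) %*% W + [1 X] %*% Aff. Single pass, no
// large temporaries.
// [[Rcpp::export]]
NumericMatrix tps_eval_cpp(NumericMatrix X, NumericMatrix A,
                           NumericMatrix W, NumericMatrix Aff) {
  const int m = X.nrow(), n = A.nrow();
  NumericMatrix out(m, 3);
  const double *ax = &A(0, 0), *ay = &A(0, 1), *az = &A(0, 2);
  const double *w0 = &W(0, 0), *w1 = &W(0, 1), *w2 = &W(0, 2);
  for (int i = 0; i < m; ++i) {
    const double x = X(i, 0), y = X(i, 1), z = X(i, 2);
    double o0 = Aff(0, 0) + Aff(1, 0) * x + Aff(2, 0) * y + Aff(3, 0) * z;
    double o1 = Aff(0, 1) + Aff(1, 1) * x + Aff(2, 1) * y + Aff(3, 1) * z;
    double o2 = Aff(0, 2) + Aff(1, 2) * x + Aff(2, 2) * y + Aff(3, 2) * z;
    for (int j = 0; j < n; ++j) {
      const double dx = x - ax[j], dy = y - ay[j], dz = z - az[j];
      const double r = -sqrt(dx * dx + dy * dy + dz * dz);
      o0 += r * w0[j];
      o1 += r * w1[j];
      o2 += r * w2[j];
    }
    out(i, 0) = o0;
    out(i, 1) = o1;
    out(i, 2) = o2;
  }
  return out;
}
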