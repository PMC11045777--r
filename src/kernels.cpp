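#include <Rcpp.h>
using namespace Rcpp;

// Gaussian kernel matrix K[i,j] = exp(-||x_i - y_j||^2 / (2 sigma^2))
// for 2D point sets X (n x 2) and Y (m x 2).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_mat(NumericMatrix X, NumericMatrix Y, double sigma) {
  int n = X.nrow(), m = Y.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j) {
    double y0 = Y(j, 0), y1 = Y(j, 1);
    for (int i = 0; i < n; ++i) {
      double d0 = X(i, 0) - y0, d1 = X(i, 1) - y1;
      K(i, j) = std::exp(-(d0 * d0 + d1 * d1) * inv2s2);
    }
  }
  return K;
}

// K(X, Y) %*% A without returning K; A is m x d.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_mv(NumericMatrix X, NumericMatrix Y, double sigma,
                           NumericMatrix A) {
  int n = X.nrow(), m = Y.nrow(), d = A.ncol();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericMatrix out(n, d);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1);
    for (int j = 0; j < m; ++j) {
      double d0 = x0 - Y(j, 0), d1 = x1 - Y(j, 1);
      double k = std::exp(-(d0 * d0 + d1 * d1) * inv2s2);
      for (int c = 0; c < d; ++c) out(i, c) += k * A(j, c);
    }
  }
  return out;
}

// Gradient contraction sum_j C[i,j] * dK(x_i, y_j)/dx_i, returned n x 2,
// with dK/dx = -K * (x - y) / sigma^2. C is n x m.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_grad_x(NumericMatrix X, NumericMatrix Y, double sigma,
                               NumericMatrix C) {
  int n = X.nrow(), m = Y.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double invs2 = 1.0 / (sigma * sigma);
  NumericMatrix G(n, 2);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1), g0 = 0.0, g1 = 0.0;
    for (int j = 0; j < m; ++j) {
      double d0 = x0 - Y(j, 0), d1 = x1 - Y(j, 1);
      double k = std::exp(-(d0 * d0 + d1 * d1) * inv2s2) * C(i, j) * invs2;
      g0 -= k * d0;
      g1 -= k * d1;
    }
    G(i, 0) = g0;
    G(i, 1) = g1;
  }
  return G;
}

// As cpp_gauss_grad_x but with the kernel matrix K precomputed:
// G_i = sum_j C[i,j] * K[i,j] * -(x_i - y_j) / sigma^2.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_grad_xK(NumericMatrix X, NumericMatrix Y,
                                NumericMatrix K, NumericMatrix C,
                                double sigma) {
  int n = X.nrow(), m = Y.nrow();
  double invs2 = 1.0 / (sigma * sigma);
  NumericMatrix G(n, 2);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1), g0 = 0.0, g1 = 0.0;
    for (int j = 0; j < m; ++j) {
      double k = K(i, j) * C(i, j) * invs2;
      g0 -= k * (x0 - Y(j, 0));
      g1 -= k * (x1 - Y(j, 1));
    }
    G(i, 0) = g0;
    G(i, 1) = g1;
  }
  return G;
}

// Jacobian of the RKHS velocity field v(x) = sum_k K(x, q_k) a_k evaluated
// at each row of X: returns n x 4 matrix (dv1/dx1, dv1/dx2, dv2/dx1, dv2/dx2).
// [[Rcpp::export]]
NumericMatrix cpp_velocity_jac(NumericMatrix X, NumericMatrix Q, double sigma,
                               NumericMatrix A) {
  int n = X.nrow(), m = Q.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double invs2 = 1.0 / (sigma * sigma);
  NumericMatrix J(n, 4);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1);
    double j11 = 0.0, j12 = 0.0, j21 = 0.0, j22 = 0.0;
    for (int k = 0; k < m; ++k) {
      double d0 = x0 - Q(k, 0), d1 = x1 - Q(k, 1);
      double g = -std::exp(-(d0 * d0 + d1 * d1) * inv2s2) * invs2;
      j11 += g * d0 * A(k, 0);
      j12 += g * d1 * A(k, 0);
      j21 += g * d0 * A(k, 1);
      j22 += g * d1 * A(k, 1);
    }
    J(i, 0) = j11;
    J(i, 1) = j12;
    J(i, 2) = j21;
    J(i, 3) = j22;
  }
  return J;
}

// Minimum squared euclidean distance from each row of X to the point set Y.
// [[Rcpp::export]]
NumericVector cpp_min_sq_dist(NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow(), m = Y.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d0 = x0 - Y(j, 0), d1 = x1 - Y(j, 1);
      double d = d0 * d0 + d1 * d1;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Index (1-based) of the nearest row of Y for each row of X; ties broken by
// the lowest index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow(), m = Y.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double x0 = X(i, 0), x1 = X(i, 1);
    double best = R_PosInf;
    int arg = 1;
    for (int j = 0; j < m; ++j) {
      double d0 = x0 - Y(j, 0), d1 = x1 - Y(j, 1);
      double d = d0 * d0 + d1 * d1;
      if (d < best) {
        best = d;
        arg = j + 1;
      }
    }
    out[i] = arg;
  }
  return out;
}
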