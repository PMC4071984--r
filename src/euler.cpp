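#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step Euler integration of the EMU labeling ODE.
//
// State: one MDV matrix Z_s (unknown EMUs x mass channels) per EMU size.
// Derivative per size: dZ_s = diag(invX) * (A_s Z_s - B_s Y_s), where the
// Y_s rows are either fixed (carbon sources) or convolutions of current
// smaller-size rows.  All derivatives are evaluated on the pre-step state,
// then every row is renormalized to sum 1 (per-step standardization).
//
// spec: list over sizes, each with A, B, Yfix, conv, invX, Z0.
// record_steps: step counts at which to snapshot the state (0 = initial).

static void convolve_into(const std::vector<double>& a,
                          const std::vector<double>& b,
                          std::vector<double>& out) {
  std::fill(out.begin(), out.end(), 0.0);
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      out[i + j] += a[i] * b[j];
}

// [[Rcpp::export]]
List euler_inst_cpp(List spec, int nsteps, double h, IntegerVector record_steps) {
  int S = spec.size();
  std::vector<int> n(S), m(S), w(S);
  std::vector<NumericMatrix> A(S), B(S), Yfix(S);
  std::vector<List> conv(S);
  std::vector<NumericVector> invX(S);
  std::vector<std::vector<double> > Z(S), Znew(S), Y(S);

  for (int s = 0; s < S; ++s) {
    List sp = spec[s];
    A[s] = as<NumericMatrix>(sp["A"]);
    B[s] = as<NumericMatrix>(sp["B"]);
    Yfix[s] = as<NumericMatrix>(sp["Yfix"]);
    conv[s] = as<List>(sp["conv"]);
    invX[s] = as<NumericVector>(sp["invX"]);
    NumericMatrix Z0 = as<NumericMatrix>(sp["Z0"]);
    n[s] = Z0.nrow();
    w[s] = Z0.ncol();
    m[s] = Yfix[s].nrow();
    Z[s].resize((size_t)n[s] * w[s]);
    Znew[s].resize((size_t)n[s] * w[s]);
    for (int i = 0; i < n[s]; ++i)
      for (int c = 0; c < w[s]; ++c)
        Z[s][(size_t)i * w[s] + c] = Z0(i, c);
    Y[s].resize((size_t)m[s] * w[s]);
    for (int j = 0; j < m[s]; ++j)
      for (int c = 0; c < w[s]; ++c)
        Y[s][(size_t)j * w[s] + c] = Yfix[s](j, c);
  }

  // map step -> record slot(s)
  int nrec = record_steps.size();
  List out(nrec);
  std::vector<double> pa, pb, pc;

  auto snapshot = [&](int slot) {
    List per(S);
    for (int s = 0; s < S; ++s) {
      NumericMatrix M(n[s], w[s]);
      for (int i = 0; i < n[s]; ++i)
        for (int c = 0; c < w[s]; ++c)
          M(i, c) = Z[s][(size_t)i * w[s] + c];
      per[s] = M;
    }
    out[slot] = per;
  };

  for (int r = 0; r < nrec; ++r)
    if (record_steps[r] == 0) snapshot(r);

  for (int step = 1; step <= nsteps; ++step) {
    // refresh dynamic convolution rows of Y from the current state
    for (int s = 0; s < S; ++s) {
      int nc = conv[s].size();
      for (int q = 0; q < nc; ++q) {
        List cv = conv[s][q];
        int row = as<int>(cv["row"]) - 1;
        int ak = as<int>(cv["a_kind"]);
        int bk = as<int>(cv["b_kind"]);
        if (ak == 1) {
          NumericVector f = as<NumericVector>(cv["a_fix"]);
          pa.assign(f.begin(), f.end());
        } else {
          int asz = as<int>(cv["a_size"]) - 1, arow = as<int>(cv["a_row"]) - 1;
          pa.assign(Z[asz].begin() + (size_t)arow * w[asz],
                    Z[asz].begin() + (size_t)(arow + 1) * w[asz]);
        }
        if (bk == 1) {
          NumericVector f = as<NumericVector>(cv["b_fix"]);
          pb.assign(f.begin(), f.end());
        } else {
          int bsz = as<int>(cv["b_size"]) - 1, brow = as<int>(cv["b_row"]) - 1;
          pb.assign(Z[bsz].begin() + (size_t)brow * w[bsz],
                    Z[bsz].begin() + (size_t)(brow + 1) * w[bsz]);
        }
        pc.resize(pa.size() + pb.size() - 1);
        convolve_into(pa, pb, pc);
        if ((int)pc.size() != w[s]) stop("convolution width mismatch");
        for (int c = 0; c < w[s]; ++c)
          Y[s][(size_t)row * w[s] + c] = pc[c];
      }
    }
    // derivative from pre-step state, then update + renormalize
    for (int s = 0; s < S; ++s) {
      const NumericMatrix& As = A[s];
      const NumericMatrix& Bs = B[s];
      for (int i = 0; i < n[s]; ++i) {
        double ix = invX[s][i];
        for (int c = 0; c < w[s]; ++c) {
          double acc = 0.0;
          for (int j = 0; j < n[s]; ++j)
            acc += As(i, j) * Z[s][(size_t)j * w[s] + c];
          for (int j = 0; j < m[s]; ++j)
            acc -= Bs(i, j) * Y[s][(size_t)j * w[s] + c];
          Znew[s][(size_t)i * w[s] + c] =
            Z[s][(size_t)i * w[s] + c] + h * ix * acc;
        }
      }
    }
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < n[s]; ++i) {
        double tot = 0.0;
        for (int c = 0; c < w[s]; ++c) tot += Znew[s][(size_t)i * w[s] + c];
        if (!(tot > 0.0) || !R_finite(tot))
          stop("state diverged at step %d (size index %d)", step, s + 1);
        for (int c = 0; c < w[s]; ++c) {
          double z = Znew[s][(size_t)i * w[s] + c] / tot;
          // a standardized MDV stays near [0, 1]; large magnitudes mean
          // the explicit step is unstable for this stiffness
          if (!R_finite(z) || z > 10.0 || z < -10.0)
            stop("state diverged at step %d (size index %d)", step, s + 1);
          Z[s][(size_t)i * w[s] + c] = z;
        }
      }
    }
    for (int r = 0; r < nrec; ++r)
      if (record_steps[r] == step) snapshot(r);
  }
  return out;
}
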