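// Inner-loop kernels for the density model: im2col/col2im for the SAME-pad
// stride-1 convolutions and batched multi-head attention forward/backward.
// Shapes mirror the R side: column-major arrays in (batch, position,
// [embed,] channel) order; attention tensors are (B, L, K, H) and (B, L, L, H).

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// X: (B, L, E, Cin) -> cols: (B*L*E, kh*kw*Cin), taps ordered (dm, dn, cin)
// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector X, IntegerVector dims, int kh, int kw) {
  const int B = dims[0], L = dims[1], E = dims[2], C = dims[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)B * L * E;
  NumericMatrix cols(nrow, kh * kw * C);
  const double *x = X.begin();
  double *out = cols.begin();
  for (int dm = 0; dm < kh; ++dm) {
    for (int dn = 0; dn < kw; ++dn) {
      for (int c = 0; c < C; ++c) {
        const int col = (dm * kw + dn) * C + c;
        double *o = out + (R_xlen_t)col * nrow;
        for (int e = 0; e < E; ++e) {
          const int es = e + dn - pw;
          for (int l = 0; l < L; ++l) {
            const int ls = l + dm - ph;
            double *dst = o + ((R_xlen_t)e * L + l) * B;
            if (ls < 0 || ls >= L || es < 0 || es >= E) {
              std::memset(dst, 0, sizeof(double) * B);
            } else {
              const double *src = x + (((R_xlen_t)c * E + es) * L + ls) * B;
              std::memcpy(dst, src, sizeof(double) * B);
            }
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add transpose of cpp_im2col2d
// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix dcols, IntegerVector dims, int kh, int kw) {
  const int B = dims[0], L = dims[1], E = dims[2], C = dims[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)B * L * E;
  NumericVector dX((R_xlen_t)B * L * E * C);
  dX.attr("dim") = dims;
  const double *dc = dcols.begin();
  double *dx = dX.begin();
  for (int dm = 0; dm < kh; ++dm) {
    for (int dn = 0; dn < kw; ++dn) {
      for (int c = 0; c < C; ++c) {
        const int col = (dm * kw + dn) * C + c;
        const double *src0 = dc + (R_xlen_t)col * nrow;
        for (int e = 0; e < E; ++e) {
          const int es = e + dn - pw;
          if (es < 0 || es >= E) continue;
          for (int l = 0; l < L; ++l) {
            const int ls = l + dm - ph;
            if (ls < 0 || ls >= L) continue;
            const double *src = src0 + ((R_xlen_t)e * L + l) * B;
            double *dst = dx + (((R_xlen_t)c * E + es) * L + ls) * B;
            for (int b = 0; b < B; ++b) dst[b] += src[b];
          }
        }
      }
    }
  }
  return dX;
}

// X: (B, L, Cin) -> cols: (B*L, k*Cin), taps ordered (dm, cin)
// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector X, IntegerVector dims, int k) {
  const int B = dims[0], L = dims[1], C = dims[2];
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)B * L;
  NumericMatrix cols(nrow, k * C);
  const double *x = X.begin();
  for (int dm = 0; dm < k; ++dm) {
    for (int c = 0; c < C; ++c) {
      const int col = dm * C + c;
      double *o = cols.begin() + (R_xlen_t)col * nrow;
      for (int l = 0; l < L; ++l) {
        const int ls = l + dm - p;
        double *dst = o + (R_xlen_t)l * B;
        if (ls < 0 || ls >= L) {
          std::memset(dst, 0, sizeof(double) * B);
        } else {
          const double *src = x + ((R_xlen_t)c * L + ls) * B;
          std::memcpy(dst, src, sizeof(double) * B);
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dcols, IntegerVector dims, int k) {
  const int B = dims[0], L = dims[1], C = dims[2];
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)B * L;
  NumericVector dX((R_xlen_t)B * L * C);
  dX.attr("dim") = dims;
  for (int dm = 0; dm < k; ++dm) {
    for (int c = 0; c < C; ++c) {
      const int col = dm * C + c;
      const double *src0 = dcols.begin() + (R_xlen_t)col * nrow;
      for (int l = 0; l < L; ++l) {
        const int ls = l + dm - p;
        if (ls < 0 || ls >= L) continue;
        const double *src = src0 + (R_xlen_t)l * B;
        double *dst = dX.begin() + ((R_xlen_t)c * L + ls) * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  return dX;
}

static inline R_xlen_t qidx(int b, int l, int k, int h, int B, int L, int K) {
  return ((((R_xlen_t)h * K + k) * L + l) * B + b);
}

// Q, K, V: (B, L, Kd, H); mask: (B, L, L, H) dropout keep/scale or empty.
// Returns A = row-softmax(Q K^T / sqrt(Kd)) (pre-dropout) and
// O = (A * mask) V, both column-major. Per-(b,h) slices are staged into
// contiguous local buffers (layout [k + Kd*l]) for cache locality.
// [[Rcpp::export]]
List cpp_att_fwd(NumericVector Q, NumericVector K, NumericVector V,
                 int B, int L, int Kd, int H, NumericVector mask) {
  const bool has_mask = mask.size() > 0;
  NumericVector A((R_xlen_t)B * L * L * H);
  NumericVector O((R_xlen_t)B * L * Kd * H);
  A.attr("dim") = IntegerVector::create(B, L, L, H);
  O.attr("dim") = IntegerVector::create(B, L, Kd, H);
  const double scale = 1.0 / std::sqrt((double)Kd);
  const double *q = Q.begin(), *kk = K.begin(), *v = V.begin();
  const double *mp = has_mask ? mask.begin() : (const double *)0;
  double *ap = A.begin(), *op = O.begin();
  std::vector<double> qb(L * Kd), kb(L * Kd), vb(L * Kd), arow(L), orow(Kd);
  for (int h = 0; h < H; ++h) {
    for (int b = 0; b < B; ++b) {
      for (int k = 0; k < Kd; ++k) {
        const R_xlen_t base = (((R_xlen_t)h * Kd + k) * L) * B + b;
        for (int l = 0; l < L; ++l) {
          qb[k + Kd * l] = q[base + (R_xlen_t)l * B];
          kb[k + Kd * l] = kk[base + (R_xlen_t)l * B];
          vb[k + Kd * l] = v[base + (R_xlen_t)l * B];
        }
      }
      for (int i = 0; i < L; ++i) {
        double mx = -1e300;
        const double *qi = &qb[Kd * i];
        for (int j = 0; j < L; ++j) {
          const double *kj = &kb[Kd * j];
          double sc = 0.0;
          for (int k = 0; k < Kd; ++k) sc += qi[k] * kj[k];
          sc *= scale;
          arow[j] = sc;
          if (sc > mx) mx = sc;
        }
        double tot = 0.0;
        for (int j = 0; j < L; ++j) { arow[j] = std::exp(arow[j] - mx); tot += arow[j]; }
        for (int k = 0; k < Kd; ++k) orow[k] = 0.0;
        for (int j = 0; j < L; ++j) {
          const double a = arow[j] / tot;
          ap[(((R_xlen_t)h * L + j) * L + i) * B + b] = a;
          double ae = a;
          if (has_mask) ae *= mp[(((R_xlen_t)h * L + j) * L + i) * B + b];
          const double *vj = &vb[Kd * j];
          for (int k = 0; k < Kd; ++k) orow[k] += ae * vj[k];
        }
        for (int k = 0; k < Kd; ++k) {
          op[(((R_xlen_t)h * Kd + k) * L + i) * B + b] = orow[k];
        }
      }
    }
  }
  return List::create(Named("A") = A, Named("O") = O);
}

// Backward of the attention core; A is the pre-dropout probability tensor.
// [[Rcpp::export]]
List cpp_att_bwd(NumericVector dO, NumericVector A, NumericVector Q,
                 NumericVector K, NumericVector V,
                 int B, int L, int Kd, int H, NumericVector mask) {
  const bool has_mask = mask.size() > 0;
  NumericVector dQ((R_xlen_t)B * L * Kd * H);
  NumericVector dK((R_xlen_t)B * L * Kd * H);
  NumericVector dV((R_xlen_t)B * L * Kd * H);
  dQ.attr("dim") = IntegerVector::create(B, L, Kd, H);
  dK.attr("dim") = IntegerVector::create(B, L, Kd, H);
  dV.attr("dim") = IntegerVector::create(B, L, Kd, H);
  const double scale = 1.0 / std::sqrt((double)Kd);
  const double *q = Q.begin(), *kk = K.begin(), *v = V.begin();
  const double *dop = dO.begin(), *apg = A.begin();
  const double *mp = has_mask ? mask.begin() : (const double *)0;
  double *dqp = dQ.begin(), *dkp = dK.begin(), *dvp = dV.begin();
  std::vector<double> qb(L * Kd), kb(L * Kd), vb(L * Kd), dob(L * Kd);
  std::vector<double> dqb(L * Kd), dkb(L * Kd), dvb(L * Kd);
  std::vector<double> arow(L), mrow(L), dA(L), dS(L);
  for (int h = 0; h < H; ++h) {
    for (int b = 0; b < B; ++b) {
      for (int k = 0; k < Kd; ++k) {
        const R_xlen_t base = (((R_xlen_t)h * Kd + k) * L) * B + b;
        for (int l = 0; l < L; ++l) {
          const R_xlen_t off = base + (R_xlen_t)l * B;
          qb[k + Kd * l] = q[off];
          kb[k + Kd * l] = kk[off];
          vb[k + Kd * l] = v[off];
          dob[k + Kd * l] = dop[off];
        }
      }
      std::fill(dqb.begin(), dqb.end(), 0.0);
      std::fill(dkb.begin(), dkb.end(), 0.0);
      std::fill(dvb.begin(), dvb.end(), 0.0);
      for (int i = 0; i < L; ++i) {
        const double *doi = &dob[Kd * i];
        for (int j = 0; j < L; ++j) {
          arow[j] = apg[(((R_xlen_t)h * L + j) * L + i) * B + b];
          mrow[j] = has_mask ? mp[(((R_xlen_t)h * L + j) * L + i) * B + b] : 1.0;
          const double *vj = &vb[Kd * j];
          double *dvj = &dvb[Kd * j];
          double da = 0.0;
          const double am = arow[j] * mrow[j];
          for (int k = 0; k < Kd; ++k) {
            dvj[k] += am * doi[k];
            da += doi[k] * vj[k];
          }
          dA[j] = da * mrow[j];
        }
        // softmax backward: dS_j = A_j * (dA_j - sum_j A_j dA_j)
        double dot = 0.0;
        for (int j = 0; j < L; ++j) dot += arow[j] * dA[j];
        for (int j = 0; j < L; ++j) dS[j] = arow[j] * (dA[j] - dot);
        double *dqi = &dqb[Kd * i];
        const double *qi = &qb[Kd * i];
        for (int j = 0; j < L; ++j) {
          const double ds = dS[j] * scale;
          const double *kj = &kb[Kd * j];
          double *dkj = &dkb[Kd * j];
          for (int k = 0; k < Kd; ++k) {
            dqi[k] += ds * kj[k];
            dkj[k] += ds * qi[k];
          }
        }
      }
      for (int k = 0; k < Kd; ++k) {
        const R_xlen_t base = (((R_xlen_t)h * Kd + k) * L) * B + b;
        for (int l = 0; l < L; ++l) {
          const R_xlen_t off = base + (R_xlen_t)l * B;
          dqp[off] = dqb[k + Kd * l];
          dkp[off] = dkb[k + Kd * l];
          dvp[off] = dvb[k + Kd * l];
        }
      }
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
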