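#include <Rcpp.h>
using namespace Rcpp;

// Dense conv/pool primitives for the detector (3D) and segmenter (2D)
// networks. Array layouts follow R column-major order:
//   2D feature maps: (H, W, C, N)   H = theta (A-lines), W = r (radial)
//   3D feature maps: (D, H, W, C, N) D = pullback depth
//   2D weights:      (kh, kw, Cin, Cout)
//   3D weights:      (kd, kh, kw, Cin, Cout)
// All convolutions are 'same' (stride 1). The theta axis can be padded
// circularly (vessel wall is a cylinder); r and depth are zero-padded.

static inline int wrap(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         bool circular_h) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector y(double(H) * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double *X = x.begin(), *Wt = w.begin(), *B = b.begin();
  double *Y = y.begin();
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      double *yp = Y + ((size_t)n * Co + co) * H * W;
      for (int i = 0; i < H * W; i++) yp[i] = B[co];
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((size_t)n * C + ci) * H * W;
        const double *wp = Wt + ((size_t)co * Ci + ci) * kh * kw;
        for (int dw = 0; dw < kw; dw++)
          for (int dh = 0; dh < kh; dh++) {
            const double wv = wp[dh + kh * dw];
            if (wv == 0.0) continue;
            for (int ow = 0; ow < W; ow++) {
              int iw = ow + dw - pw;
              if (iw < 0 || iw >= W) continue;
              const double *xc = xp + (size_t)iw * H;
              double *yc = yp + (size_t)ow * H;
              for (int oh = 0; oh < H; oh++) {
                int ih = oh + dh - ph;
                if (circular_h) ih = wrap(ih, H);
                else if (ih < 0 || ih >= H) continue;
                yc[oh] += wv * xc[ih];
              }
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool circular_h) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector dx(x.size()), dw_(w.size()), db(Co);
  dx.attr("dim") = xd;
  dw_.attr("dim") = wd;
  const double *X = x.begin(), *Wt = w.begin(), *DY = dy.begin();
  double *DX = dx.begin(), *DW = dw_.begin(), *DB = db.begin();
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      const double *dyp = DY + ((size_t)n * Co + co) * H * W;
      for (int i = 0; i < H * W; i++) DB[co] += dyp[i];
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((size_t)n * C + ci) * H * W;
        double *dxp = DX + ((size_t)n * C + ci) * H * W;
        const double *wp = Wt + ((size_t)co * Ci + ci) * kh * kw;
        double *dwp = DW + ((size_t)co * Ci + ci) * kh * kw;
        for (int dw2 = 0; dw2 < kw; dw2++)
          for (int dh = 0; dh < kh; dh++) {
            const double wv = wp[dh + kh * dw2];
            double acc = 0.0;
            for (int ow = 0; ow < W; ow++) {
              int iw = ow + dw2 - pw;
              if (iw < 0 || iw >= W) continue;
              const double *xc = xp + (size_t)iw * H;
              double *dxc = dxp + (size_t)iw * H;
              const double *dyc = dyp + (size_t)ow * H;
              for (int oh = 0; oh < H; oh++) {
                int ih = oh + dh - ph;
                if (circular_h) ih = wrap(ih, H);
                else if (ih < 0 || ih >= H) continue;
                acc += dyc[oh] * xc[ih];
                dxc[ih] += dyc[oh] * wv;
              }
            }
            dwp[dh + kh * dw2] += acc;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw_, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3], Co = wd[4];
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  NumericVector y(double(D) * H * W * Co * N);
  y.attr("dim") = IntegerVector::create(D, H, W, Co, N);
  const double *X = x.begin(), *Wt = w.begin(), *B = b.begin();
  double *Y = y.begin();
  const size_t plane = (size_t)D * H * W;
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      double *yp = Y + ((size_t)n * Co + co) * plane;
      for (size_t i = 0; i < plane; i++) yp[i] = B[co];
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((size_t)n * C + ci) * plane;
        const double *wp = Wt + ((size_t)co * Ci + ci) * kd * kh * kw;
        for (int dw = 0; dw < kw; dw++)
          for (int dh = 0; dh < kh; dh++)
            for (int dd = 0; dd < kd; dd++) {
              const double wv = wp[dd + kd * (dh + kh * dw)];
              if (wv == 0.0) continue;
              for (int ow = 0; ow < W; ow++) {
                int iw = ow + dw - pw;
                if (iw < 0 || iw >= W) continue;
                for (int oh = 0; oh < H; oh++) {
                  int ih = oh + dh - ph;
                  if (ih < 0 || ih >= H) continue;
                  const double *xc = xp + ((size_t)iw * H + ih) * D;
                  double *yc = yp + ((size_t)ow * H + oh) * D;
                  for (int od = 0; od < D; od++) {
                    int id = od + dd - pd;
                    if (id < 0 || id >= D) continue;
                    yc[od] += wv * xc[id];
                  }
                }
              }
            }
      }
    }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3], Co = wd[4];
  const int pd = kd / 2, ph = kh / 2, pw = kw / 2;
  NumericVector dx(x.size()), dw_(w.size()), db(Co);
  dx.attr("dim") = xd;
  dw_.attr("dim") = wd;
  const double *X = x.begin(), *Wt = w.begin(), *DY = dy.begin();
  double *DX = dx.begin(), *DW = dw_.begin(), *DB = db.begin();
  const size_t plane = (size_t)D * H * W;
  for (int n = 0; n < N; n++)
    for (int co = 0; co < Co; co++) {
      const double *dyp = DY + ((size_t)n * Co + co) * plane;
      for (size_t i = 0; i < plane; i++) DB[co] += dyp[i];
      for (int ci = 0; ci < Ci; ci++) {
        const double *xp = X + ((size_t)n * C + ci) * plane;
        double *dxp = DX + ((size_t)n * C + ci) * plane;
        const double *wp = Wt + ((size_t)co * Ci + ci) * kd * kh * kw;
        double *dwp = DW + ((size_t)co * Ci + ci) * kd * kh * kw;
        for (int dw2 = 0; dw2 < kw; dw2++)
          for (int dh = 0; dh < kh; dh++)
            for (int dd = 0; dd < kd; dd++) {
              const double wv = wp[dd + kd * (dh + kh * dw2)];
              double acc = 0.0;
              for (int ow = 0; ow < W; ow++) {
                int iw = ow + dw2 - pw;
                if (iw < 0 || iw >= W) continue;
                for (int oh = 0; oh < H; oh++) {
                  int ih = oh + dh - ph;
                  if (ih < 0 || ih >= H) continue;
                  const double *xc = xp + ((size_t)iw * H + ih) * D;
                  double *dxc = dxp + ((size_t)iw * H + ih) * D;
                  const double *dyc = dyp + ((size_t)ow * H + oh) * D;
                  for (int od = 0; od < D; od++) {
                    int id = od + dd - pd;
                    if (id < 0 || id >= D) continue;
                    acc += dyc[od] * xc[id];
                    dxc[id] += dyc[od] * wv;
                  }
                }
              }
              dwp[dd + kd * (dh + kh * dw2)] += acc;
            }
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw_, _["db"] = db);
}

// Max pooling over (H, W) with window size s, stride s, floor division.
// idx holds 0-based flat indices into x (for unpooling / backprop).
// Ties resolve to the first maximum in column-major scan order.

// [[Rcpp::export]]
List maxpool2d_fwd(NumericVector x, int s) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / s, W2 = W / s;
  NumericVector y(double(H2) * W2 * C * N);
  NumericVector idx(y.size());
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = y.attr("dim");
  const double *X = x.begin();
  double *Y = y.begin(), *I = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < W2; ow++)
        for (int oh = 0; oh < H2; oh++) {
          double best = -1e300;
          size_t bi = 0;
          for (int dw = 0; dw < s; dw++)
            for (int dh = 0; dh < s; dh++) {
              size_t ii = base + (size_t)(ow * s + dw) * H + (oh * s + dh);
              if (X[ii] > best) { best = X[ii]; bi = ii; }
            }
          Y[o] = best;
          I[o] = (double)bi;
          o++;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
List maxpool3d_hw_fwd(NumericVector x, int s) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int H2 = H / s, W2 = W / s;
  NumericVector y(double(D) * H2 * W2 * C * N);
  NumericVector idx(y.size());
  y.attr("dim") = IntegerVector::create(D, H2, W2, C, N);
  idx.attr("dim") = y.attr("dim");
  const double *X = x.begin();
  double *Y = y.begin(), *I = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      const size_t base = ((size_t)n * C + c) * D * H * W;
      for (int ow = 0; ow < W2; ow++)
        for (int oh = 0; oh < H2; oh++)
          for (int d = 0; d < D; d++) {
            double best = -1e300;
            size_t bi = 0;
            for (int dw = 0; dw < s; dw++)
              for (int dh = 0; dh < s; dh++) {
                size_t ii = base +
                  ((size_t)(ow * s + dw) * H + (oh * s + dh)) * D + d;
                if (X[ii] > best) { best = X[ii]; bi = ii; }
              }
            Y[o] = best;
            I[o] = (double)bi;
            o++;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}
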