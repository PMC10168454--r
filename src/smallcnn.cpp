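// Small convolutional binary classifier ("small-cnn"): three 3x3 conv
// blocks (8/16/32 channels, ReLU, 2x2 average pooling), global average
// pooling, and a sigmoid head. Trained with Adam on binary cross-entropy.
// Single-threaded and fully deterministic given the seed (std::mt19937),
// so identical inputs always reproduce identical members bit for bit.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr int KC1 = 8, KC2 = 16, KC3 = 32;

struct Shape {
  int S;            // input side (divisible by 8)
  int h1, h2, h3;   // sides after each pooling stage
  // parameter offsets into the flat theta vector
  int oW1, ob1, oW2, ob2, oW3, ob3, oWd, obd, n;
  explicit Shape(int side) : S(side), h1(side / 2), h2(side / 4),
                             h3(side / 8) {
    oW1 = 0;            ob1 = oW1 + KC1 * 1 * 9;
    oW2 = ob1 + KC1;    ob2 = oW2 + KC2 * KC1 * 9;
    oW3 = ob2 + KC2;    ob3 = oW3 + KC3 * KC2 * 9;
    oWd = ob3 + KC3;    obd = oWd + KC3;
    n = obd + 1;
  }
};

// conv 3x3, stride 1, zero pad 1, over Cin -> Cout channels on an s x s grid
void conv_forward(const double* in, int cin, int s, const double* W,
                  const double* b, int cout, double* out) {
  const int area = s * s;
  for (int co = 0; co < cout; ++co)
    std::fill(out + co * area, out + (co + 1) * area, b[co]);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < cin; ++ci) {
      const double* inc = in + ci * area;
      double* outc = out + co * area;
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1;
        for (int kx = 0; kx < 3; ++kx) {
          const int dx = kx - 1;
          const double w = W[((co * cin + ci) * 3 + ky) * 3 + kx];
          const int y0 = std::max(0, -dy), y1 = std::min(s, s - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(s, s - dx);
          for (int y = y0; y < y1; ++y) {
            const double* irow = inc + (y + dy) * s + dx;
            double* orow = outc + y * s;
            for (int x = x0; x < x1; ++x) orow[x] += w * irow[x];
          }
        }
      }
    }
  }
}

// gradients of conv 3x3 pad 1: accumulates dW, db and din (din may be null)
void conv_backward(const double* in, int cin, int s, const double* W,
                   int cout, const double* dout, double* dW, double* db,
                   double* din) {
  const int area = s * s;
  for (int co = 0; co < cout; ++co) {
    const double* doc = dout + co * area;
    double acc = 0.0;
    for (int i = 0; i < area; ++i) acc += doc[i];
    db[co] += acc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* inc = in + ci * area;
      double* dinc = din ? din + ci * area : nullptr;
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1;
        for (int kx = 0; kx < 3; ++kx) {
          const int dx = kx - 1;
          const int widx = ((co * cin + ci) * 3 + ky) * 3 + kx;
          const double w = W[widx];
          double dw = 0.0;
          const int y0 = std::max(0, -dy), y1 = std::min(s, s - dy);
          const int x0 = std::max(0, -dx), x1 = std::min(s, s - dx);
          for (int y = y0; y < y1; ++y) {
            const double* irow = inc + (y + dy) * s + dx;
            const double* drow = doc + y * s;
            if (dinc) {
              double* dirow = dinc + (y + dy) * s + dx;
              for (int x = x0; x < x1; ++x) {
                dw += irow[x] * drow[x];
                dirow[x] += w * drow[x];
              }
            } else {
              for (int x = x0; x < x1; ++x) dw += irow[x] * drow[x];
            }
          }
          dW[widx] += dw;
        }
      }
    }
  }
}

void relu_inplace(double* a, int n) {
  for (int i = 0; i < n; ++i) if (a[i] < 0.0) a[i] = 0.0;
}

void avgpool2_forward(const double* in, int c, int s, double* out) {
  const int h = s / 2;
  for (int ci = 0; ci < c; ++ci) {
    const double* inc = in + ci * s * s;
    double* outc = out + ci * h * h;
    for (int y = 0; y < h; ++y)
      for (int x = 0; x < h; ++x)
        outc[y * h + x] = 0.25 * (inc[(2 * y) * s + 2 * x] +
                                  inc[(2 * y) * s + 2 * x + 1] +
                                  inc[(2 * y + 1) * s + 2 * x] +
                                  inc[(2 * y + 1) * s + 2 * x + 1]);
  }
}

void avgpool2_backward(const double* dout, int c, int s, double* din) {
  const int h = s / 2;
  for (int ci = 0; ci < c; ++ci) {
    const double* doc = dout + ci * h * h;
    double* dic = din + ci * s * s;
    for (int y = 0; y < h; ++y)
      for (int x = 0; x < h; ++x) {
        const double g = 0.25 * doc[y * h + x];
        dic[(2 * y) * s + 2 * x] += g;
        dic[(2 * y) * s + 2 * x + 1] += g;
        dic[(2 * y + 1) * s + 2 * x] += g;
        dic[(2 * y + 1) * s + 2 * x + 1] += g;
      }
  }
}

struct Workspace {
  std::vector<double> a1, p1, a2, p2, a3, p3, g;
  std::vector<double> d1, dp1, d2, dp2, d3, dp3, dg;
  explicit Workspace(const Shape& sh)
      : a1(KC1 * sh.S * sh.S), p1(KC1 * sh.h1 * sh.h1),
        a2(KC2 * sh.h1 * sh.h1), p2(KC2 * sh.h2 * sh.h2),
        a3(KC3 * sh.h2 * sh.h2), p3(KC3 * sh.h3 * sh.h3), g(KC3),
        d1(a1.size()), dp1(p1.size()), d2(a2.size()), dp2(p2.size()),
        d3(a3.size()), dp3(p3.size()), dg(KC3) {}
};

// forward pass for one image; returns the sigmoid probability
double forward(const double* x, const Shape& sh, const double* th,
               Workspace& w) {
  conv_forward(x, 1, sh.S, th + sh.oW1, th + sh.ob1, KC1, w.a1.data());
  relu_inplace(w.a1.data(), (int)w.a1.size());
  avgpool2_forward(w.a1.data(), KC1, sh.S, w.p1.data());
  conv_forward(w.p1.data(), KC1, sh.h1, th + sh.oW2, th + sh.ob2, KC2,
               w.a2.data());
  relu_inplace(w.a2.data(), (int)w.a2.size());
  avgpool2_forward(w.a2.data(), KC2, sh.h1, w.p2.data());
  conv_forward(w.p2.data(), KC2, sh.h2, th + sh.oW3, th + sh.ob3, KC3,
               w.a3.data());
  relu_inplace(w.a3.data(), (int)w.a3.size());
  avgpool2_forward(w.a3.data(), KC3, sh.h2, w.p3.data());
  const int a3n = sh.h3 * sh.h3;
  double logit = th[sh.obd];
  for (int c = 0; c < KC3; ++c) {
    double acc = 0.0;
    const double* pc = w.p3.data() + c * a3n;
    for (int i = 0; i < a3n; ++i) acc += pc[i];
    w.g[c] = acc / a3n;
    logit += th[sh.oWd + c] * w.g[c];
  }
  return 1.0 / (1.0 + std::exp(-logit));
}

// backward pass for one image (after forward); dlogit = p - y (BCE+sigmoid)
void backward(const double* x, const Shape& sh, const double* th,
              Workspace& w, double dlogit, double* grad) {
  const int a3n = sh.h3 * sh.h3;
  grad[sh.obd] += dlogit;
  for (int c = 0; c < KC3; ++c) {
    grad[sh.oWd + c] += dlogit * w.g[c];
    w.dg[c] = dlogit * th[sh.oWd + c];
  }
  std::fill(w.dp3.begin(), w.dp3.end(), 0.0);
  for (int c = 0; c < KC3; ++c) {
    const double g = w.dg[c] / a3n;
    double* dpc = w.dp3.data() + c * a3n;
    for (int i = 0; i < a3n; ++i) dpc[i] = g;
  }
  std::fill(w.d3.begin(), w.d3.end(), 0.0);
  avgpool2_backward(w.dp3.data(), KC3, sh.h2, w.d3.data());
  for (size_t i = 0; i < w.d3.size(); ++i) if (w.a3[i] <= 0.0) w.d3[i] = 0.0;
  std::fill(w.dp2.begin(), w.dp2.end(), 0.0);
  conv_backward(w.p2.data(), KC2, sh.h2, th + sh.oW3, KC3, w.d3.data(),
                grad + sh.oW3, grad + sh.ob3, w.dp2.data());
  std::fill(w.d2.begin(), w.d2.end(), 0.0);
  avgpool2_backward(w.dp2.data(), KC2, sh.h1, w.d2.data());
  for (size_t i = 0; i < w.d2.size(); ++i) if (w.a2[i] <= 0.0) w.d2[i] = 0.0;
  std::fill(w.dp1.begin(), w.dp1.end(), 0.0);
  conv_backward(w.p1.data(), KC1, sh.h1, th + sh.oW2, KC2, w.d2.data(),
                grad + sh.oW2, grad + sh.ob2, w.dp1.data());
  std::fill(w.d1.begin(), w.d1.end(), 0.0);
  avgpool2_backward(w.dp1.data(), KC1, sh.S, w.d1.data());
  for (size_t i = 0; i < w.d1.size(); ++i) if (w.a1[i] <= 0.0) w.d1[i] = 0.0;
  conv_backward(x, 1, sh.S, th + sh.oW1, KC1, w.d1.data(),
                grad + sh.oW1, grad + sh.ob1, nullptr);
}

// Mann-Whitney AUC with midrank tie handling (internal readout for
// validation-checkpoint selection)
double auc_mw(const std::vector<double>& s, const std::vector<int>& y) {
  const int n = (int)s.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }
  double rsum = 0.0;
  long npos = 0;
  for (int k = 0; k < n; ++k)
    if (y[k] == 1) { rsum += rank[k]; ++npos; }
  const long nneg = n - npos;
  if (npos == 0 || nneg == 0) return 0.5;
  return (rsum - npos * (npos + 1.0) / 2.0) / ((double)npos * nneg);
}

List theta_to_list(const std::vector<double>& th, const Shape& sh) {
  auto slice = [&](int from, int len) {
    return NumericVector(th.begin() + from, th.begin() + from + len);
  };
  return List::create(
      _["W1"] = slice(sh.oW1, KC1 * 9), _["b1"] = slice(sh.ob1, KC1),
      _["W2"] = slice(sh.oW2, KC2 * KC1 * 9), _["b2"] = slice(sh.ob2, KC2),
      _["W3"] = slice(sh.oW3, KC3 * KC2 * 9), _["b3"] = slice(sh.ob3, KC3),
      _["Wd"] = slice(sh.oWd, KC3), _["bd"] = slice(sh.obd, 1));
}

std::vector<double> list_to_theta(List weights, const Shape& sh) {
  std::vector<double> th(sh.n);
  auto put = [&](const char* name, int from, int len) {
    NumericVector v = weights[name];
    if ((int)v.size() != len) stop("weight block '%s' has wrong length", name);
    std::copy(v.begin(), v.end(), th.begin() + from);
  };
  put("W1", sh.oW1, KC1 * 9); put("b1", sh.ob1, KC1);
  put("W2", sh.oW2, KC2 * KC1 * 9); put("b2", sh.ob2, KC2);
  put("W3", sh.oW3, KC3 * KC2 * 9); put("b3", sh.ob3, KC3);
  put("Wd", sh.oWd, KC3); put("bd", sh.obd, 1);
  return th;
}

void check_side(int side) {
  if (side < 16 || side % 8 != 0)
    stop("image side must be a multiple of 8 and at least 16");
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix Xtr, IntegerVector ytr, NumericMatrix Xval,
                   IntegerVector yval, int side, int epochs, int batch_size,
                   double lr, int seed) {
  check_side(side);
  const Shape sh(side);
  const int npix = side * side;
  if (Xtr.nrow() != npix || Xval.nrow() != npix)
    stop("pixel rows do not match side*side");
  const int ntr = Xtr.ncol(), nval = Xval.ncol();
  if (ntr != (int)ytr.size() || nval != (int)yval.size())
    stop("label length mismatch");
  if (epochs < 1) stop("epochs must be >= 1");
  if (batch_size < 1) stop("batch_size must be >= 1");

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  std::vector<double> th(sh.n, 0.0);
  // He-normal initialisation for conv weights, smaller for the head
  auto init_block = [&](int from, int len, double sd) {
    for (int i = 0; i < len; ++i) th[from + i] = sd * nd(rng);
  };
  init_block(sh.oW1, KC1 * 9, std::sqrt(2.0 / 9.0));
  init_block(sh.oW2, KC2 * KC1 * 9, std::sqrt(2.0 / (9.0 * KC1)));
  init_block(sh.oW3, KC3 * KC2 * 9, std::sqrt(2.0 / (9.0 * KC2)));
  init_block(sh.oWd, KC3, std::sqrt(1.0 / KC3));

  std::vector<double> grad(sh.n), m(sh.n, 0.0), v(sh.n, 0.0);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Workspace w(sh);
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  std::vector<double> best_th = th;
  double best_auc = -1.0;
  int best_epoch = 0;
  NumericVector history(epochs);
  std::vector<double> vs(nval);
  std::vector<int> vy(yval.begin(), yval.end());

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < ntr; start += batch_size) {
      const int end = std::min(ntr, start + batch_size);
      const int bs = end - start;
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int k = start; k < end; ++k) {
        const int i = order[k];
        const double* x = &Xtr(0, i);
        const double p = forward(x, sh, th.data(), w);
        backward(x, sh, th.data(), w, (p - (double)ytr[i]) / bs, grad.data());
      }
      ++t;
      const double corr = std::sqrt(1.0 - std::pow(b2, (double)t)) /
                          (1.0 - std::pow(b1, (double)t));
      for (int i = 0; i < sh.n; ++i) {
        m[i] = b1 * m[i] + (1.0 - b1) * grad[i];
        v[i] = b2 * v[i] + (1.0 - b2) * grad[i] * grad[i];
        th[i] -= lr * corr * m[i] / (std::sqrt(v[i]) + eps);
      }
      Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i < nval; ++i) vs[i] = forward(&Xval(0, i), sh,
                                                   th.data(), w);
    const double a = auc_mw(vs, vy);
    history[ep] = a;
    if (a > best_auc) { best_auc = a; best_epoch = ep + 1; best_th = th; }
  }

  return List::create(_["weights"] = theta_to_list(best_th, sh),
                      _["val_auc_history"] = history,
                      _["best_epoch"] = best_epoch,
                      _["best_val_auc"] = best_auc);
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(NumericMatrix X, int side, List weights) {
  check_side(side);
  const Shape sh(side);
  if (X.nrow() != side * side) stop("pixel rows do not match side*side");
  const std::vector<double> th = list_to_theta(weights, sh);
  const int n = X.ncol();
  Workspace w(sh);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = forward(&X(0, i), sh, th.data(), w);
  return out;
}
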