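// Dense feed-forward nets for the multiethnic learning benchmark:
//  - pyramid classifier (ReLU hidden layers, logistic output, dropout,
//    L1/L2 penalties, mini-batch SGD with Nesterov momentum)
//  - stacked denoising autoencoder (masking corruption, squared error)
//  - CCSA domain adaptation (joint classification + contrastive
//    semantic-alignment / separation pair losses)
// All randomness flows through a self-contained 64-bit Mersenne Twister so
// results are bit-reproducible for a given seed, independently of R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double EPS_CLIP = 1e-7;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed + 0x9E3779B97F4A7C15ULL) {}
  // uniform in [0, 1) from the top 53 bits
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) {  // 0 .. n-1
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  void shuffle(std::vector<int>& v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = unif_int(i + 1);
      std::swap(v[i], v[j]);
    }
  }
  // Fill a dropout mask with 0 or 1/(1-p). p = 0.5 uses raw random bits
  // (exactly Bernoulli(1/2), one 64-bit draw per 64 entries).
  void fill_dropout(arma::mat& M, double p) {
    double keep = 1.0 / (1.0 - p);
    double* ptr = M.memptr();
    arma::uword n = M.n_elem;
    if (p == 0.5) {
      uint64_t bits = 0;
      int avail = 0;
      for (arma::uword i = 0; i < n; ++i) {
        if (avail == 0) {
          bits = eng();
          avail = 64;
        }
        ptr[i] = (bits & 1ULL) ? keep : 0.0;
        bits >>= 1;
        --avail;
      }
    } else {
      for (arma::uword i = 0; i < n; ++i)
        ptr[i] = unif() < p ? 0.0 : keep;
    }
  }
};

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  size_t n_layers() const { return W.size(); }
};

Net glorot_init(const std::vector<int>& sizes, Rng& rng) {
  Net net;
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    double lim = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
    arma::mat W(sizes[l], sizes[l + 1]);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i)
        W(i, j) = (2.0 * rng.unif() - 1.0) * lim;
    net.W.push_back(W);
    net.b.push_back(arma::rowvec(sizes[l + 1], arma::fill::zeros));
  }
  return net;
}

Net net_from_lists(const List& Wl, const List& bl) {
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(as<arma::mat>(Wl[l]));
    net.b.push_back(as<arma::rowvec>(bl[l]));
  }
  return net;
}

List net_to_list(const Net& net) {
  List Wl(net.n_layers()), bl(net.n_layers());
  for (size_t l = 0; l < net.n_layers(); ++l) {
    Wl[l] = net.W[l];
    bl[l] = net.b[l];
  }
  return List::create(_["W"] = Wl, _["b"] = bl);
}

arma::mat relu_m(const arma::mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

arma::vec sigmoid_v(const arma::vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

double cross_entropy(const arma::vec& p, const arma::vec& y) {
  arma::vec pc = arma::clamp(p, EPS_CLIP, 1.0 - EPS_CLIP);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

// L1/L2 penalty value over connection weights only (never biases).
// l2_squared = true gives the weight-decay convention lambda2 * ||W||^2;
// false gives the literal unsquared Frobenius norm over all layers.
double penalty_value(const Net& net, double lambda1, double lambda2,
                     bool l2_squared) {
  double a1 = 0.0, s2 = 0.0;
  for (const arma::mat& W : net.W) {
    a1 += arma::accu(arma::abs(W));
    s2 += arma::accu(arma::square(W));
  }
  double pen = lambda1 * a1;
  pen += l2_squared ? lambda2 * s2 : lambda2 * std::sqrt(s2);
  return pen;
}

void add_penalty_grad(const Net& net, std::vector<arma::mat>& gW,
                      double lambda1, double lambda2, bool l2_squared) {
  if (lambda1 == 0 && lambda2 == 0) return;
  double s2 = 0.0;
  if (!l2_squared && lambda2 > 0) {
    for (const arma::mat& W : net.W) s2 += arma::accu(arma::square(W));
    s2 = std::sqrt(s2);
  }
  double c2 = l2_squared ? 2.0 * lambda2 : (s2 > 0 ? lambda2 / s2 : 0.0);
  for (size_t l = 0; l < net.n_layers(); ++l) {
    const double* w = net.W[l].memptr();
    double* g = gW[l].memptr();
    arma::uword n = net.W[l].n_elem;
    for (arma::uword i = 0; i < n; ++i)
      g[i] += lambda1 * ((w[i] > 0) - (w[i] < 0)) + c2 * w[i];
  }
}

// Forward + backward pass for the classifier net on one batch.
// Dropout masks (inverted scaling) are applied to hidden activations when
// dropout_p > 0 and rng != nullptr; pass rng = nullptr for a deterministic
// pass. Returns the batch loss (mean cross-entropy + penalties).
double classifier_loss_grad(const Net& net, const arma::mat& Xb,
                            const arma::vec& yb, double lambda1,
                            double lambda2, bool l2_squared, double dropout_p,
                            Rng* rng, std::vector<arma::mat>& gW,
                            std::vector<arma::rowvec>& gb,
                            bool with_penalty_value = true) {
  size_t L = net.n_layers();          // hidden layers = L - 1
  double n = static_cast<double>(Xb.n_rows);
  std::vector<arma::mat> A(L + 1), Z(L), M(L);
  A[0] = Xb;
  for (size_t l = 0; l + 1 < L; ++l) {
    Z[l] = A[l] * net.W[l];
    Z[l].each_row() += net.b[l];
    A[l + 1] = relu_m(Z[l]);
    if (dropout_p > 0 && rng != nullptr) {
      M[l].set_size(A[l + 1].n_rows, A[l + 1].n_cols);
      rng->fill_dropout(M[l], dropout_p);
      A[l + 1] %= M[l];
    }
  }
  arma::vec zo = A[L - 1] * net.W[L - 1] + net.b[L - 1](0);
  arma::vec p = sigmoid_v(zo);
  double loss = cross_entropy(p, yb);
  if (with_penalty_value)
    loss += penalty_value(net, lambda1, lambda2, l2_squared);

  gW.assign(L, arma::mat());
  gb.assign(L, arma::rowvec());
  arma::vec dzo = (p - yb) / n;
  gW[L - 1] = A[L - 1].t() * dzo;
  gb[L - 1] = arma::rowvec(1);
  gb[L - 1](0) = arma::accu(dzo);
  arma::mat dA = dzo * net.W[L - 1].t();
  for (int l = static_cast<int>(L) - 2; l >= 0; --l) {
    if (dropout_p > 0 && rng != nullptr) dA %= M[l];
    arma::mat dZ = dA % (Z[l] > 0);
    gW[l] = A[l].t() * dZ;
    gb[l] = arma::sum(dZ, 0);
    if (l > 0) dA = dZ * net.W[l].t();
  }
  add_penalty_grad(net, gW, lambda1, lambda2, l2_squared);
  return loss;
}

// Nesterov momentum update in the velocity formulation of the cited
// implementation: v <- mu v - lr g ; w <- w + mu v - lr g.
void nesterov_step(Net& net, std::vector<arma::mat>& vW,
                   std::vector<arma::rowvec>& vb,
                   const std::vector<arma::mat>& gW,
                   const std::vector<arma::rowvec>& gb, double lr, double mu) {
  for (size_t l = 0; l < net.n_layers(); ++l) {
    vW[l] = mu * vW[l] - lr * gW[l];
    vb[l] = mu * vb[l] - lr * gb[l];
    net.W[l] += mu * vW[l] - lr * gW[l];
    net.b[l] += mu * vb[l] - lr * gb[l];
  }
}

void init_velocity(const Net& net, std::vector<arma::mat>& vW,
                   std::vector<arma::rowvec>& vb) {
  vW.clear();
  vb.clear();
  for (size_t l = 0; l < net.n_layers(); ++l) {
    vW.push_back(arma::mat(net.W[l].n_rows, net.W[l].n_cols, arma::fill::zeros));
    vb.push_back(arma::rowvec(net.b[l].n_elem, arma::fill::zeros));
  }
}

}  // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   const IntegerVector& hidden, double lr, double lr_decay,
                   int batch_size, int max_iter, double momentum,
                   double dropout_p, double lambda1, double lambda2,
                   bool l2_squared, int seed, Nullable<List> init = R_NilValue) {
  int n = X.n_rows, d = X.n_cols;
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);

  Net net;
  if (init.isNotNull()) {
    List init_l(init);
    net = net_from_lists(init_l["W"], init_l["b"]);
  } else {
    net = glorot_init(sizes, rng);
  }

  std::vector<arma::mat> vW, gW;
  std::vector<arma::rowvec> vb, gb;
  init_velocity(net, vW, vb);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector loss_log(max_iter);

  for (int ep = 0; ep < max_iter; ++ep) {
    double cur_lr = lr / (1.0 + lr_decay * ep);
    rng.shuffle(idx);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      arma::uvec rows(stop - start);
      for (int i = start; i < stop; ++i) rows[i - start] = idx[i];
      arma::mat Xb = X.rows(rows);
      arma::vec yb = y.elem(rows);
      double loss = classifier_loss_grad(net, Xb, yb, lambda1, lambda2,
                                         l2_squared, dropout_p, &rng, gW, gb,
                                         false);
      nesterov_step(net, vW, vb, gW, gb, cur_lr, momentum);
      ep_loss += loss;
      ++n_batches;
    }
    // logged epoch loss: mean batch cross-entropy plus the penalty at the
    // epoch-end weights (penalties evaluated once per epoch for speed)
    loss_log[ep] = ep_loss / n_batches +
                   penalty_value(net, lambda1, lambda2, l2_squared);
    if (!std::isfinite(loss_log[ep]))
      stop("training diverged (non-finite loss) at epoch %d", ep + 1);
  }

  List out = net_to_list(net);
  out["loss_log"] = loss_log;
  return out;
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const List& Wl, const List& bl, const arma::mat& X) {
  Net net = net_from_lists(Wl, bl);
  arma::mat A = X;
  for (size_t l = 0; l + 1 < net.n_layers(); ++l) {
    arma::mat Z = A * net.W[l];
    Z.each_row() += net.b[l];
    A = relu_m(Z);
  }
  arma::vec zo = A * net.W.back() + net.b.back()(0);
  return sigmoid_v(zo);
}

// Deterministic (dropout-free) full-batch loss and analytic gradients,
// for finite-difference verification and convex-limit checks.
// [[Rcpp::export]]
List mlp_loss_grad_cpp(const List& Wl, const List& bl, const arma::mat& X,
                       const arma::vec& y, double lambda1, double lambda2,
                       bool l2_squared) {
  Net net = net_from_lists(Wl, bl);
  std::vector<arma::mat> gW;
  std::vector<arma::rowvec> gb;
  double loss = classifier_loss_grad(net, X, y, lambda1, lambda2, l2_squared,
                                     0.0, nullptr, gW, gb);
  List gWl(gW.size()), gbl(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    gWl[l] = gW[l];
    gbl[l] = gb[l];
  }
  return List::create(_["loss"] = loss, _["gW"] = gWl, _["gb"] = gbl);
}

// [[Rcpp::export]]
arma::mat corrupt_matrix_cpp(const arma::mat& X, double level, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  arma::mat Xc = X;
  for (arma::uword j = 0; j < Xc.n_cols; ++j)
    for (arma::uword i = 0; i < Xc.n_rows; ++i)
      if (rng.unif() < level) Xc(i, j) = 0.0;
  return Xc;
}

// Denoising autoencoder: layer sizes d -> hidden... -> d, ReLU on hidden
// layers, linear output, squared reconstruction error averaged over the
// batch. Inputs are corrupted by masking to zero at rate `corruption` per
// presentation; the reconstruction target is the clean input.
// [[Rcpp::export]]
List ae_train_cpp(const arma::mat& X, const IntegerVector& hidden,
                  double corruption, double lr, int batch_size, int max_iter,
                  double momentum, int seed) {
  int n = X.n_rows, d = X.n_cols;
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(d);
  Net net = glorot_init(sizes, rng);
  size_t L = net.n_layers();

  std::vector<arma::mat> vW, gW(L);
  std::vector<arma::rowvec> vb, gb(L);
  init_velocity(net, vW, vb);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector loss_log(max_iter);

  for (int ep = 0; ep < max_iter; ++ep) {
    rng.shuffle(idx);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n);
      arma::uvec rows(stop - start);
      for (int i = start; i < stop; ++i) rows[i - start] = idx[i];
      arma::mat Xb = X.rows(rows);
      double nb = Xb.n_rows;
      arma::mat Xc = Xb;
      if (corruption > 0)
        for (arma::uword jj = 0; jj < Xc.n_cols; ++jj)
          for (arma::uword ii = 0; ii < Xc.n_rows; ++ii)
            if (rng.unif() < corruption) Xc(ii, jj) = 0.0;

      std::vector<arma::mat> A(L + 1), Z(L);
      A[0] = Xc;
      for (size_t l = 0; l + 1 < L; ++l) {
        Z[l] = A[l] * net.W[l];
        Z[l].each_row() += net.b[l];
        A[l + 1] = relu_m(Z[l]);
      }
      arma::mat Xhat = A[L - 1] * net.W[L - 1];
      Xhat.each_row() += net.b[L - 1];
      double loss = arma::accu(arma::square(Xhat - Xb)) / nb;

      arma::mat dZ = 2.0 * (Xhat - Xb) / nb;
      gW[L - 1] = A[L - 1].t() * dZ;
      gb[L - 1] = arma::sum(dZ, 0);
      arma::mat dA = dZ * net.W[L - 1].t();
      for (int l = static_cast<int>(L) - 2; l >= 0; --l) {
        arma::mat dZl = dA % (Z[l] > 0);
        gW[l] = A[l].t() * dZl;
        gb[l] = arma::sum(dZl, 0);
        if (l > 0) dA = dZl * net.W[l].t();
      }
      nesterov_step(net, vW, vb, gW, gb, lr, momentum);
      ep_loss += loss;
      ++n_batches;
    }
    loss_log[ep] = ep_loss / n_batches;
    if (!std::isfinite(loss_log[ep]))
      stop("autoencoder training diverged (non-finite loss) at epoch %d", ep + 1);
  }
  List out = net_to_list(net);
  out["loss_log"] = loss_log;
  return out;
}

// [[Rcpp::export]]
arma::mat ae_reconstruct_cpp(const List& Wl, const List& bl,
                             const arma::mat& X) {
  Net net = net_from_lists(Wl, bl);
  arma::mat A = X;
  for (size_t l = 0; l + 1 < net.n_layers(); ++l) {
    arma::mat Z = A * net.W[l];
    Z.each_row() += net.b[l];
    A = relu_m(Z);
  }
  arma::mat Xhat = A * net.W.back();
  Xhat.each_row() += net.b.back();
  return Xhat;
}

namespace {

// Contrastive pair losses over all source x target pairs of one batch,
// using clean (dropout-free) embeddings. Also accumulates gradients
// w.r.t. the embeddings, scaled by `scale` (gamma), into dEs / dEt.
void pair_losses_grad(const arma::mat& Es, const arma::mat& Et,
                      const arma::vec& ys, const arma::vec& yt, double margin,
                      double scale, double& Lsa, double& Ls, arma::mat& dEs,
                      arma::mat& dEt) {
  int ns = Es.n_rows, nt = Et.n_rows;
  int n_sa = 0, n_s = 0;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < nt; ++j)
      (ys[i] == yt[j]) ? ++n_sa : ++n_s;
  Lsa = 0.0;
  Ls = 0.0;
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < nt; ++j) {
      arma::rowvec diff = Es.row(i) - Et.row(j);
      double dist = std::sqrt(arma::accu(arma::square(diff)));
      if (ys[i] == yt[j]) {
        Lsa += 0.5 * dist * dist / n_sa;
        dEs.row(i) += scale * diff / n_sa;
        dEt.row(j) -= scale * diff / n_sa;
      } else {
        double gap = margin - dist;
        if (gap > 0) {
          Ls += 0.5 * gap * gap / n_s;
          if (dist > 0) {
            arma::rowvec g = -(gap / (dist * n_s)) * diff;
            dEs.row(i) += scale * g;
            dEt.row(j) -= scale * g;
          }
        }
      }
    }
  }
}

}  // namespace

// CCSA: embedding g = ReLU(X We + be) (one hidden layer), classifier
// h = sigmoid(Z wo + bo) with dropout on the classification path only.
// Loss per batch: (1 - gamma) * L_C(combined source+target batch)
//                 + gamma * (L_SA + L_S) over all cross-domain pairs.
// [[Rcpp::export]]
List ccsa_train_cpp(const arma::mat& Xs, const arma::vec& ys,
                    const arma::mat& Xt, const arma::vec& yt, int hidden_nodes,
                    double gamma, double margin, double lr, double momentum,
                    int batch_size, int max_iter, double dropout_p, int seed) {
  int ns = Xs.n_rows, nt = Xt.n_rows, d = Xs.n_cols;
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> sizes = {d, hidden_nodes, 1};
  Net net = glorot_init(sizes, rng);

  std::vector<arma::mat> vW, gW(2);
  std::vector<arma::rowvec> vb, gb(2);
  init_velocity(net, vW, vb);

  std::vector<int> idx(ns);
  for (int i = 0; i < ns; ++i) idx[i] = i;
  NumericMatrix loss_log(max_iter, 4);
  colnames(loss_log) = CharacterVector::create("total", "lc", "lsa", "ls");

  for (int ep = 0; ep < max_iter; ++ep) {
    rng.shuffle(idx);
    double ep_tot = 0, ep_lc = 0, ep_lsa = 0, ep_ls = 0;
    int n_batches = 0;
    for (int start = 0; start < ns; start += batch_size) {
      int stop = std::min(start + batch_size, ns);
      int bs = stop - start;
      arma::uvec srows(bs), trows(bs);
      for (int i = 0; i < bs; ++i) {
        srows[i] = idx[start + i];
        trows[i] = rng.unif_int(nt);
      }
      arma::mat Xsb = Xs.rows(srows), Xtb = Xt.rows(trows);
      arma::vec ysb = ys.elem(srows), ytb = yt.elem(trows);

      // embeddings
      arma::mat Zs = Xsb * net.W[0];
      Zs.each_row() += net.b[0];
      arma::mat Es = relu_m(Zs);
      arma::mat Zt = Xtb * net.W[0];
      Zt.each_row() += net.b[0];
      arma::mat Et = relu_m(Zt);

      // classification path with dropout on embeddings
      arma::mat Ms(Es.n_rows, Es.n_cols), Mt(Et.n_rows, Et.n_cols);
      if (dropout_p > 0) {
        rng.fill_dropout(Ms, dropout_p);
        rng.fill_dropout(Mt, dropout_p);
      } else {
        Ms.ones();
        Mt.ones();
      }
      arma::mat A = arma::join_cols(Es % Ms, Et % Mt);
      arma::vec yb = arma::join_cols(ysb, ytb);
      double ncomb = A.n_rows;
      arma::vec zo = A * net.W[1] + net.b[1](0);
      arma::vec p = sigmoid_v(zo);
      double lc = cross_entropy(p, yb);

      arma::vec dzo = (1.0 - gamma) * (p - yb) / ncomb;
      gW[1] = A.t() * dzo;
      gb[1] = arma::rowvec(1);
      gb[1](0) = arma::accu(dzo);
      arma::mat dA = dzo * net.W[1].t();
      arma::mat dEs = dA.rows(0, bs - 1) % Ms;
      arma::mat dEt = dA.rows(bs, 2 * bs - 1) % Mt;

      double lsa, ls;
      pair_losses_grad(Es, Et, ysb, ytb, margin, gamma, lsa, ls, dEs, dEt);

      arma::mat dZs = dEs % (Zs > 0), dZt = dEt % (Zt > 0);
      gW[0] = Xsb.t() * dZs + Xtb.t() * dZt;
      gb[0] = arma::sum(dZs, 0) + arma::sum(dZt, 0);
      nesterov_step(net, vW, vb, gW, gb, lr, momentum);

      double total = (1.0 - gamma) * lc + gamma * (lsa + ls);
      ep_tot += total;
      ep_lc += lc;
      ep_lsa += lsa;
      ep_ls += ls;
      ++n_batches;
    }
    loss_log(ep, 0) = ep_tot / n_batches;
    loss_log(ep, 1) = ep_lc / n_batches;
    loss_log(ep, 2) = ep_lsa / n_batches;
    loss_log(ep, 3) = ep_ls / n_batches;
    if (!std::isfinite(loss_log(ep, 0)))
      stop("CCSA training diverged (non-finite loss) at epoch %d", ep + 1);
  }
  List out = net_to_list(net);
  out["loss_log"] = loss_log;
  return out;
}

// Deterministic evaluation of the CCSA loss components on fixed batches.
// [[Rcpp::export]]
List ccsa_eval_loss_cpp(const List& Wl, const List& bl, const arma::mat& Xs,
                        const arma::vec& ys, const arma::mat& Xt,
                        const arma::vec& yt, double gamma, double margin) {
  Net net = net_from_lists(Wl, bl);
  arma::mat Zs = Xs * net.W[0];
  Zs.each_row() += net.b[0];
  arma::mat Es = relu_m(Zs);
  arma::mat Zt = Xt * net.W[0];
  Zt.each_row() += net.b[0];
  arma::mat Et = relu_m(Zt);
  arma::mat A = arma::join_cols(Es, Et);
  arma::vec yb = arma::join_cols(ys, yt);
  arma::vec p = sigmoid_v(A * net.W[1] + net.b[1](0));
  double lc = cross_entropy(p, yb);
  arma::mat dEs(Es.n_rows, Es.n_cols, arma::fill::zeros);
  arma::mat dEt(Et.n_rows, Et.n_cols, arma::fill::zeros);
  double lsa, ls;
  pair_losses_grad(Es, Et, ys, yt, margin, 0.0, lsa, ls, dEs, dEt);
  return List::create(_["total"] = (1.0 - gamma) * lc + gamma * (lsa + ls),
                      _["lc"] = lc, _["lsa"] = lsa, _["ls"] = ls);
}
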