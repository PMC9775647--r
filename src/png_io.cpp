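// Minimal lossless PNG codec for 8-bit grayscale / RGB / RGBA rasters.
//
// The surrounding R installation ships no PNG reader, so the package
// carries its own: plain (non-interlaced) 8-bit images only, zlib for
// DEFLATE and CRC-32.  Pixel data crosses the R boundary as a raw vector
// in scanline order (rows top to bottom, channels interleaved).

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const unsigned char PNG_SIG[8] =
  {0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A};

static void put_u32(std::vector<unsigned char> &buf, uint32_t v) {
  buf.push_back((v >> 24) & 0xFF); buf.push_back((v >> 16) & 0xFF);
  buf.push_back((v >> 8) & 0xFF);  buf.push_back(v & 0xFF);
}

static void write_chunk(FILE *fp, const char type[4],
                        const unsigned char *data, uint32_t len) {
  std::vector<unsigned char> head;
  put_u32(head, len);
  fwrite(head.data(), 1, 4, fp);
  fwrite(type, 1, 4, fp);
  if (len) fwrite(data, 1, len, fp);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, reinterpret_cast<const Bytef *>(type), 4);
  if (len) crc = crc32(crc, data, len);
  std::vector<unsigned char> tail;
  put_u32(tail, static_cast<uint32_t>(crc));
  fwrite(tail.data(), 1, 4, fp);
}

// [[Rcpp::export]]
void write_png_cpp(std::string path, RawVector data, int width, int height,
                   int channels) {
  if (channels != 1 && channels != 3 && channels != 4)
    stop("PNG writer supports 1 (gray), 3 (RGB) or 4 (RGBA) channels");
  if (width < 1 || height < 1) stop("image dimensions must be positive");
  const size_t stride = static_cast<size_t>(width) * channels;
  if (static_cast<size_t>(data.size()) != stride * height)
    stop("pixel buffer size does not match width * height * channels");

  // filter type 0 (None) for every scanline
  std::vector<unsigned char> raw(height * (stride + 1));
  for (int y = 0; y < height; ++y) {
    raw[y * (stride + 1)] = 0;
    std::memcpy(&raw[y * (stride + 1) + 1], &data[y * stride], stride);
  }
  uLongf comp_len = compressBound(raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), raw.size(), 6) != Z_OK)
    stop("zlib compression failed");

  FILE *fp = std::fopen(path.c_str(), "wb");
  if (!fp) stop("cannot open '%s' for writing", path.c_str());
  fwrite(PNG_SIG, 1, 8, fp);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, width); put_u32(ihdr, height);
  ihdr.push_back(8);                                     // bit depth
  ihdr.push_back(channels == 1 ? 0 : (channels == 3 ? 2 : 6));  // color type
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);  // deflate/adaptive/no interlace
  write_chunk(fp, "IHDR", ihdr.data(), ihdr.size());
  write_chunk(fp, "IDAT", comp.data(), comp_len);
  write_chunk(fp, "IEND", NULL, 0);
  std::fclose(fp);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
List read_png_cpp(std::string path) {
  FILE *fp = std::fopen(path.c_str(), "rb");
  if (!fp) stop("cannot open '%s'", path.c_str());
  unsigned char sig[8];
  if (fread(sig, 1, 8, fp) != 8 || std::memcmp(sig, PNG_SIG, 8) != 0) {
    std::fclose(fp); stop("'%s' is not a PNG file", path.c_str());
  }
  int width = 0, height = 0, bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  for (;;) {
    unsigned char head[8];
    if (fread(head, 1, 8, fp) != 8) { std::fclose(fp); stop("truncated PNG"); }
    uint32_t len = (uint32_t(head[0]) << 24) | (uint32_t(head[1]) << 16) |
                   (uint32_t(head[2]) << 8) | head[3];
    char type[5] = {char(head[4]), char(head[5]), char(head[6]), char(head[7]), 0};
    std::vector<unsigned char> payload(len);
    if (len && fread(payload.data(), 1, len, fp) != len) {
      std::fclose(fp); stop("truncated PNG chunk");
    }
    std::fseek(fp, 4, SEEK_CUR);  // skip CRC
    if (std::strcmp(type, "IHDR") == 0) {
      width  = (payload[0] << 24) | (payload[1] << 16) | (payload[2] << 8) | payload[3];
      height = (payload[4] << 24) | (payload[5] << 16) | (payload[6] << 8) | payload[7];
      bit_depth = payload[8]; color_type = payload[9]; interlace = payload[12];
    } else if (std::strcmp(type, "IDAT") == 0) {
      idat.insert(idat.end(), payload.begin(), payload.end());
    } else if (std::strcmp(type, "IEND") == 0) {
      break;
    }
  }
  std::fclose(fp);
  if (bit_depth != 8)
    stop("only 8-bit PNG is supported (got bit depth %d)", bit_depth);
  if (interlace != 0) stop("interlaced PNG is not supported");
  int channels;
  switch (color_type) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 6: channels = 4; break;
    default: stop("unsupported PNG color type %d", color_type);
  }
  const size_t stride = static_cast<size_t>(width) * channels;
  std::vector<unsigned char> raw(height * (stride + 1));
  uLongf raw_len = raw.size();
  if (uncompress(raw.data(), &raw_len, idat.data(), idat.size()) != Z_OK ||
      raw_len != raw.size())
    stop("PNG decompression failed");

  RawVector out(stride * height);
  std::vector<unsigned char> prev(stride, 0);
  for (int y = 0; y < height; ++y) {
    const unsigned char filter = raw[y * (stride + 1)];
    unsigned char *line = &raw[y * (stride + 1) + 1];
    for (size_t x = 0; x < stride; ++x) {
      const int a = x >= static_cast<size_t>(channels) ? line[x - channels] : 0;
      const int b = prev[x];
      const int c = x >= static_cast<size_t>(channels) ? prev[x - channels] : 0;
      int v = line[x];
      switch (filter) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: v += paeth(a, b, c); break;
        default: stop("unsupported PNG filter type %d", filter);
      }
      line[x] = static_cast<unsigned char>(v & 0xFF);
    }
    std::memcpy(&out[y * stride], line, stride);
    std::memcpy(prev.data(), line, stride);
  }
  return List::create(_["width"] = width, _["height"] = height,
                      _["channels"] = channels, _["data"] = out);
}
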